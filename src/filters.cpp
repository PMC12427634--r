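#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median filter with edge replication. Window must be odd (checked in R).
// [[Rcpp::export]]
IntegerMatrix cpp_median_filter(const IntegerMatrix& img, const int window) {
  const int h = img.nrow(), w = img.ncol(), r = window / 2;
  const int n = window * window;
  IntegerMatrix out(h, w);
  std::vector<int> buf(n);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      int k = 0;
      for (int dx = -r; dx <= r; ++dx) {
        int xx = std::min(std::max(x + dx, 0), w - 1);
        for (int dy = -r; dy <= r; ++dy) {
          int yy = std::min(std::max(y + dy, 0), h - 1);
          buf[k++] = img(yy, xx);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      out(y, x) = buf[n / 2];
    }
  }
  return out;
}

// 8-connected component labeling of a {0,255} matrix. Labels are assigned in
// raster-scan (row-major) order of first encounter, starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& bin) {
  const int h = bin.nrow(), w = bin.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  int next = 0;
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      if (bin(y, x) == 0 || lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      stack.push_back(y + h * x);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cy = idx % h, cx = idx / h;
        for (int dx = -1; dx <= 1; ++dx) {
          int nx = cx + dx;
          if (nx < 0 || nx >= w) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int ny = cy + dy;
            if (ny < 0 || ny >= h || (dx == 0 && dy == 0)) continue;
            if (bin(ny, nx) != 0 && lab(ny, nx) == 0) {
              lab(ny, nx) = next;
              stack.push_back(ny + h * nx);
            }
          }
        }
      }
    }
  }
  return lab;
}
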