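# Minimal 5x7 bitmap font for rasterizing overlay labels (no graphics device
# involved, so overlays are deterministic and testable pixel-for-pixel).
.font5x7 <- local({
  g <- list(
    "0" = c("01110", "10001", "10011", "10101", "11001", "10001", "01110"),
    "1" = c("00100", "01100", "00100", "00100", "00100", "00100", "01110"),
    "2" = c("01110", "10001", "00001", "00010", "00100", "01000", "11111"),
    "3" = c("11111", "00010", "00100", "00010", "00001", "10001", "01110"),
    "4" = c("00010", "00110", "01010", "10010", "11111", "00010", "00010"),
    "5" = c("11111", "10000", "11110", "00001", "00001", "10001", "01110"),
    "6" = c("00110", "01000", "10000", "11110", "10001", "10001", "01110"),
    "7" = c("11111", "00001", "00010", "00100", "01000", "01000", "01000"),
    "8" = c("01110", "10001", "10001", "01110", "10001", "10001", "01110"),
    "9" = c("01110", "10001", "10001", "01111", "00001", "00010", "01100"),
    "." = c("00000", "00000", "00000", "00000", "00000", "01100", "01100"),
    "-" = c("00000", "00000", "00000", "11111", "00000", "00000", "00000"),
    " " = c("00000", "00000", "00000", "00000", "00000", "00000", "00000"),
    "A" = c("01110", "10001", "10001", "11111", "10001", "10001", "10001"),
    "C" = c("01110", "10001", "10000", "10000", "10000", "10001", "01110"),
    "E" = c("11111", "10000", "10000", "11110", "10000", "10000", "11111"),
    "F" = c("11111", "10000", "10000", "11110", "10000", "10000", "10000"),
    "M" = c("10001", "11011", "10101", "10101", "10001", "10001", "10001"),
    "N" = c("10001", "11001", "10101", "10011", "10001", "10001", "10001"),
    "O" = c("01110", "10001", "10001", "10001", "10001", "10001", "01110"),
    "R" = c("11110", "10001", "10001", "11110", "10100", "10010", "10001")
  )
  lapply(g, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]] == "1")))
    m
  })
})

# Rasterize `text` into a 0/1 matrix (7 rows, 6 cols per glyph incl. spacing).
render_text_mask <- function(text) {
  chars <- strsplit(toupper(text), "")[[1]]
  glyphs <- lapply(chars, function(ch) {
    g <- .font5x7[[ch]]
    if (is.null(g)) g <- .font5x7[[" "]]
    cbind(g, 0L)
  })
  do.call(cbind, glyphs)
}

# Stamp white pixels of `mask` into img with top-left at (x, y), 0-based.
stamp_mask <- function(img, mask, x, y, value = 255L) {
  h <- nrow(img); w <- ncol(img)
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) return(img)
  yy <- y + idx[, 1]  # 1-based row in image = y + row index (0-based top-left)
  xx <- x + idx[, 2]
  keep <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
  img[cbind(yy[keep], xx[keep])] <- value
  img
}

draw_rect_outline <- function(img, x_min, y_min, x_max, y_max, value = 255L) {
  h <- nrow(img); w <- ncol(img)
  x0 <- clamp(floor(x_min), 0, w - 1) + 1
  x1 <- clamp(ceiling(x_max) - 1, 0, w - 1) + 1
  y0 <- clamp(floor(y_min), 0, h - 1) + 1
  y1 <- clamp(ceiling(y_max) - 1, 0, h - 1) + 1
  img[y0, x0:x1] <- value
  img[y1, x0:x1] <- value
  img[y0:y1, x0] <- value
  img[y0:y1, x1] <- value
  img
}

# Bresenham segment between two 0-based pixel points.
draw_segment <- function(img, p1, p2, value = 255L) {
  x0 <- round(p1[[1]]); y0 <- round(p1[[2]])
  x1 <- round(p2[[1]]); y1 <- round(p2[[2]])
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  n <- max(dx, dy)
  xs <- round(seq(x0, x1, length.out = n + 1))
  ys <- round(seq(y0, y1, length.out = n + 1))
  h <- nrow(img); w <- ncol(img)
  keep <- xs >= 0 & xs < w & ys >= 0 & ys < h
  img[cbind(ys[keep] + 1, xs[keep] + 1)] <- value
  img
}

#' Render detections and measurements onto an image
#'
#' Draws each detection box as a white outline with a bitmap-font caption
#' `"<label> <confidence>"` (confidence to two decimals) above the box, and
#' each measurement as a white segment between its two endpoints. With empty
#' inputs the image is returned unmodified.
#'
#' @param image Gray image matrix.
#' @param detections Detection tibble (see [detections()]); may be empty or
#'   `NULL`.
#' @param measurements A [measurement_report()] or measurement tibble; may be
#'   `NULL`.
#' @return A gray image matrix with the graphics burned in.
#' @export
render_overlay <- function(image, detections = NULL, measurements = NULL) {
  img <- assert_gray(image)
  if (!is.null(detections) && nrow(detections) > 0) {
    for (i in seq_len(nrow(detections))) {
      d <- detections[i, ]
      img <- draw_rect_outline(img, d$x_min, d$y_min, d$x_max, d$y_max)
      caption <- sprintf("%s %.2f", d$label, d$confidence)
      mask <- render_text_mask(caption)
      tx <- round(d$x_min)
      ty <- round(d$y_min) - nrow(mask) - 2
      if (ty < 0) ty <- round(d$y_min) + 2
      img <- stamp_mask(img, mask, tx, ty)
    }
  }
  m <- measurements
  if (inherits(m, "measurement_report")) m <- m$measurements
  if (!is.null(m) && nrow(m) > 0) {
    for (i in seq_len(nrow(m))) {
      img <- draw_segment(img, c(m$p1_x[i], m$p1_y[i]), c(m$p2_x[i], m$p2_y[i]))
    }
  }
  img
}
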