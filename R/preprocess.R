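#' Preprocessing configuration
#'
#' Parameters of the binarization pipeline. `target_size` is the standard
#' square size every radiograph is resampled to before analysis;
#' `median_window` the side of the median denoising window (odd);
#' `clahe_clip`/`clahe_tiles` the CLAHE clip factor and tile-grid side;
#' `adaptive_block` the side of the local-mean window (odd) and
#' `adaptive_offset` the amount subtracted from the local mean before
#' comparison. `use_he`/`use_clahe` switch the two contrast-enhancement
#' stages individually; `adaptive_method` selects mean or Gaussian-weighted
#' local averaging.
#'
#' @param target_size Standard image side in pixels (default 512).
#' @param median_window Odd window size for the median filter (default 3).
#' @param clahe_clip Positive clip-limit factor (default 2).
#' @param clahe_tiles Tile-grid side (default 8).
#' @param adaptive_block Odd local-mean window (default 31).
#' @param adaptive_offset Offset subtracted from the local mean (default 5).
#' @param use_he,use_clahe Enable global HE / CLAHE (defaults `TRUE`).
#' @param adaptive_method `"mean"` (default) or `"gaussian"`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_size = 512L, median_window = 3L,
                              clahe_clip = 2, clahe_tiles = 8L,
                              adaptive_block = 31L, adaptive_offset = 5,
                              use_he = TRUE, use_clahe = TRUE,
                              adaptive_method = c("mean", "gaussian")) {
  adaptive_method <- match.arg(adaptive_method)
  if (target_size < 32) abort("`target_size` must be at least 32.")
  if (median_window < 3 || median_window %% 2 == 0) {
    abort("`median_window` must be odd and >= 3.")
  }
  if (adaptive_block < 3 || adaptive_block %% 2 == 0) {
    abort("`adaptive_block` must be odd and >= 3.")
  }
  if (clahe_clip <= 0) abort("`clahe_clip` must be positive.")
  if (clahe_tiles < 1) abort("`clahe_tiles` must be at least 1.")
  structure(
    list(
      target_size = as.integer(target_size), median_window = as.integer(median_window),
      clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
      adaptive_block = as.integer(adaptive_block), adaptive_offset = adaptive_offset,
      use_he = isTRUE(use_he), use_clahe = isTRUE(use_clahe),
      adaptive_method = adaptive_method
    ),
    class = "preprocess_config"
  )
}

#' Resize an image to the standard square size
#'
#' Bilinear resampling with pixel-center alignment; constants are preserved
#' exactly and output values are clamped to `[0, 255]`.
#'
#' @param image Gray image matrix.
#' @param target Output side length in pixels.
#' @return A `target` x `target` gray image.
#' @export
resize_to_standard <- function(image, target = 512L) {
  img <- assert_gray(image)
  if (target < 1) abort("`target` must be at least 1.")
  if (nrow(img) == target && ncol(img) == target) return(img)
  out <- resize_axis(resize_axis(img, target, axis = 1), target, axis = 2)
  gray_image(clamp(round(out), 0, 255))
}

# Bilinear resample along one axis (1 = rows, 2 = cols); edge-clamped.
resize_axis <- function(m, target, axis) {
  n_in <- dim(m)[axis]
  if (n_in == target) return(m)
  s <- (seq_len(target) - 0.5) * n_in / target - 0.5
  i0 <- clamp(floor(s), 0, n_in - 1)
  i1 <- pmin(i0 + 1, n_in - 1)
  w <- clamp(s - i0, 0, 1)
  if (axis == 1) {
    m[i0 + 1, , drop = FALSE] * (1 - w) + m[i1 + 1, , drop = FALSE] * w
  } else {
    t(t(m[, i0 + 1, drop = FALSE]) * (1 - w) + t(m[, i1 + 1, drop = FALSE]) * w)
  }
}

#' Median filter with edge replication
#'
#' Each output pixel is the median of the `window` x `window` neighborhood
#' of the input; pixels outside the image take the value of the nearest edge
#' pixel. Effective against salt-and-pepper noise while preserving edges.
#'
#' @param image Gray image matrix.
#' @param window Odd window side, at least 3.
#' @return Filtered gray image.
#' @export
median_filter <- function(image, window = 3L) {
  img <- assert_gray(image)
  if (window %% 2 == 0 || window < 3) abort("`window` must be odd and >= 3.")
  cpp_median_filter(img, as.integer(window))
}

# Histogram-equalization lookup table from 256-bin counts; identity when the
# histogram is degenerate (single occupied bin or empty).
he_lut <- function(counts) {
  n <- sum(counts)
  if (n == 0 || sum(counts > 0) < 2) return(0:255)
  cdf <- cumsum(counts)
  cdf_min <- cdf[which(counts > 0)[1]]
  if (n == cdf_min) return(0:255)
  as.integer(round((cdf - cdf_min) / (n - cdf_min) * 255))
}

#' Global histogram equalization
#'
#' Standard cumulative-distribution remapping of intensities; the mapping is
#' monotone, so pixel rank order is preserved up to ties. A constant image is
#' returned unchanged.
#'
#' @param image Gray image matrix.
#' @return Equalized gray image.
#' @export
equalize_hist <- function(image) {
  img <- assert_gray(image)
  counts <- tabulate(as.vector(img) + 1L, nbins = 256L)
  lut <- he_lut(counts)
  out <- img
  out[] <- lut[img + 1L]
  out
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization: the image is divided into a
#' `tiles` x `tiles` grid, each tile's histogram is clipped at
#' `clip` times the mean bin count (the excess redistributed uniformly),
#' an equalization mapping is built per tile, and every pixel is remapped by
#' bilinear interpolation between the mappings of the four nearest tile
#' centers. With `tiles = 1` and a large `clip` this degenerates to
#' [equalize_hist()].
#'
#' @param image Gray image matrix.
#' @param clip Positive clip-limit factor (default 2).
#' @param tiles Tile-grid side (default 8).
#' @return Enhanced gray image.
#' @export
clahe <- function(image, clip = 2, tiles = 8L) {
  img <- assert_gray(image)
  if (clip <= 0) abort("`clip` must be positive.")
  if (tiles < 1) abort("`tiles` must be at least 1.")
  tiles <- as.integer(tiles)
  h <- nrow(img); w <- ncol(img)
  ys <- tile_breaks(h, tiles); xs <- tile_breaks(w, tiles)
  # per-tile LUTs: array [256, tiles_y, tiles_x]
  luts <- array(0L, dim = c(256L, tiles, tiles))
  for (ti in seq_len(tiles)) {
    for (tj in seq_len(tiles)) {
      tile <- img[(ys[ti] + 1):ys[ti + 1], (xs[tj] + 1):xs[tj + 1], drop = FALSE]
      counts <- tabulate(as.vector(tile) + 1L, nbins = 256L)
      # a degenerate (single-intensity or empty) tile maps identically;
      # clip redistribution would otherwise invent contrast from nothing
      luts[, ti, tj] <- if (sum(counts > 0) < 2) 0:255 else he_lut(clip_histogram(counts, clip))
    }
  }
  cy <- (ys[-length(ys)] + ys[-1]) / 2 - 0.5
  cx <- (xs[-length(xs)] + xs[-1]) / 2 - 0.5
  iy <- interp_index(seq_len(h) - 1, cy)
  ix <- interp_index(seq_len(w) - 1, cx)
  v <- as.vector(img) + 1L
  I0 <- rep(iy$i0, times = w); I1 <- rep(iy$i1, times = w)
  WY <- rep(iy$w, times = w)
  J0 <- rep(ix$i0, each = h); J1 <- rep(ix$i1, each = h)
  WX <- rep(ix$w, each = h)
  lk <- function(ti, tj) luts[v + 256L * (ti - 1L) + 256L * tiles * (tj - 1L)]
  out <- (1 - WY) * (1 - WX) * lk(I0, J0) + (1 - WY) * WX * lk(I0, J1) +
    WY * (1 - WX) * lk(I1, J0) + WY * WX * lk(I1, J1)
  res <- img
  res[] <- as.integer(clamp(round(out), 0, 255))
  res
}

tile_breaks <- function(n, tiles) {
  round(seq(0, n, length.out = tiles + 1))
}

# Clip histogram at clip * mean bin count; redistribute the excess uniformly
# (remainder to the lowest bins) so the total count is preserved.
clip_histogram <- function(counts, clip) {
  limit <- max(1, floor(clip * sum(counts) / length(counts)))
  excess <- sum(pmax(counts - limit, 0))
  if (excess == 0) return(counts)
  out <- pmin(counts, limit)
  out <- out + excess %/% length(counts)
  rem <- excess %% length(counts)
  if (rem > 0) out[seq_len(rem)] <- out[seq_len(rem)] + 1
  out
}

# For positions p (0-based) and sorted centers c: bracketing center indices
# (1-based) and interpolation weight toward the upper one.
interp_index <- function(p, centers) {
  k <- length(centers)
  i0 <- findInterval(p, centers)
  i0 <- clamp(i0, 1L, max(k - 1L, 1L))
  i1 <- pmin(i0 + 1L, k)
  span <- centers[i1] - centers[i0]
  w <- ifelse(span > 0, clamp((p - centers[i0]) / ifelse(span > 0, span, 1), 0, 1), 0)
  list(i0 = as.integer(i0), i1 = as.integer(i1), w = w)
}

#' Otsu's optimal global threshold
#'
#' Returns the intensity `t` in `[0, 255]` that maximizes the between-class
#' variance of the partition `{v <= t}` / `{v > t}` — equivalently, minimizes
#' the within-class variance. Ties are broken toward the lowest maximizing
#' threshold, making the result deterministic.
#'
#' @param image Gray image matrix with at least two distinct values.
#' @return Integer threshold in `[0, 255]`.
#' @export
otsu_threshold <- function(image) {
  img <- assert_gray(image)
  counts <- tabulate(as.vector(img) + 1L, nbins = 256L)
  if (sum(counts > 0) < 2) abort("degenerate histogram: image has a single intensity.")
  p <- counts / sum(counts)
  v <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * v)
  mu <- m0[256]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (mu * w0[valid] - m0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  as.integer(which.max(sigma_b) - 1L)
}

#' Adaptive mean thresholding
#'
#' A pixel becomes foreground (255) iff its value exceeds the mean of its
#' `block` x `block` neighborhood (edge-replicated) minus `offset`. With
#' `method = "gaussian"` the neighborhood mean is Gaussian-weighted
#' (`sigma = block / 6`).
#'
#' @param image Gray image matrix.
#' @param block Odd window side, at least 3.
#' @param offset Value subtracted from the local mean.
#' @param method `"mean"` (default) or `"gaussian"`.
#' @return Binary image.
#' @export
adaptive_threshold <- function(image, block = 31L, offset = 5,
                               method = c("mean", "gaussian")) {
  method <- match.arg(method)
  img <- assert_gray(image)
  if (block %% 2 == 0 || block < 3) abort("`block` must be odd and >= 3.")
  local_mean <- if (method == "mean") {
    box_mean_replicate(img, block)
  } else {
    gaussian_blur_raw(img, sigma = block / 6, radius = (block - 1L) %/% 2L)
  }
  out <- img
  out[] <- ifelse(img > local_mean - offset, 255L, 0L)
  out
}

# Box mean over block x block with edge replication, via integral image.
box_mean_replicate <- function(img, block) {
  r <- (block - 1L) %/% 2L
  p <- pad_replicate(img, r)
  s <- apply(p, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  s <- rbind(0, cbind(0, s))
  h <- nrow(img); w <- ncol(img)
  y0 <- seq_len(h); y1 <- y0 + block - 1L
  x0 <- seq_len(w); x1 <- x0 + block - 1L
  (s[y1 + 1, x1 + 1, drop = FALSE] - s[y0, x1 + 1, drop = FALSE] -
    s[y1 + 1, x0, drop = FALSE] + s[y0, x0, drop = FALSE]) / (block * block)
}

pad_replicate <- function(m, r) {
  if (r == 0) return(m)
  ri <- clamp(seq(1 - r, nrow(m) + r), 1, nrow(m))
  ci <- clamp(seq(1 - r, ncol(m) + r), 1, ncol(m))
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian smoothing with edge replication; returns doubles.
gaussian_blur_raw <- function(img, sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0 || radius < 1) return(img + 0)
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_replicate(img + 0, radius)
  h <- nrow(img); w <- ncol(img)
  tmp <- matrix(0, h, ncol(p))
  for (j in seq_along(k)) {
    tmp <- tmp + k[j] * p[(j - 1) + seq_len(h), , drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (j in seq_along(k)) {
    out <- out + k[j] * tmp[, (j - 1) + seq_len(w), drop = FALSE]
  }
  out
}

#' Gaussian blur
#'
#' Separable Gaussian smoothing with edge replication; kernel radius
#' `ceiling(3 * sigma)`.
#'
#' @param image Gray image matrix.
#' @param sigma Standard deviation in pixels.
#' @return Smoothed gray image.
#' @export
gaussian_blur <- function(image, sigma = 1) {
  img <- assert_gray(image)
  gray_image(clamp(round(gaussian_blur_raw(img, sigma)), 0, 255))
}

#' Full binarization pipeline
#'
#' Standardizes, denoises, enhances and binarizes a radiograph:
#' resize to `target_size` -> median filter -> global HE -> CLAHE ->
#' adaptive threshold AND (pixel >= Otsu threshold). The logical AND uses
#' Otsu's global split to refine the adaptive mask, suppressing flat
#' background regions that local thresholding alone marks as foreground.
#'
#' @param image Gray image matrix.
#' @param config A [preprocess_config()].
#' @return A binary image of size `target_size` x `target_size`.
#' @export
binarize_pipeline <- function(image, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  img <- resize_to_standard(image, config$target_size)
  img <- median_filter(img, config$median_window)
  if (config$use_he) img <- equalize_hist(img)
  if (config$use_clahe) img <- clahe(img, config$clahe_clip, config$clahe_tiles)
  adaptive <- adaptive_threshold(img, config$adaptive_block, config$adaptive_offset,
    method = config$adaptive_method
  )
  t_otsu <- otsu_threshold(img)
  out <- img
  out[] <- ifelse(adaptive == 255L & img >= t_otsu, 255L, 0L)
  out
}
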