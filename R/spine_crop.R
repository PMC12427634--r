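#' Row-scan localization of the cervical spine
#'
#' The spine region of a binarized radiograph is located by scanning rows of
#' the binary image: the row with the fewest (but at least one) white pixels
#' anchors the lateral bounds, which are expanded to the first/last
#' black-to-white transitions plus contiguous run growth and padded; the
#' vertical bounds are the extent of foreground within that column band,
#' padded likewise. All coordinates are 0-based, half-open.
#'
#' @name spine_crop
NULL

#' @describeIn spine_crop Number of white (255) pixels per row, top to bottom.
#' @param binary Binary image matrix.
#' @return Integer vector of length `nrow(binary)`.
#' @export
row_white_counts <- function(binary) {
  b <- assert_binary(binary)
  as.integer(rowSums(b == 255L))
}

#' @describeIn spine_crop Topmost row (0-based) among rows with the minimum
#'   strictly-positive white count. Errors if no row has foreground.
#' @param counts Integer vector of per-row white counts.
#' @export
select_anchor_row <- function(counts) {
  pos <- counts > 0
  if (!any(pos)) abort("no foreground: all rows have zero white pixels.")
  m <- min(counts[pos])
  as.integer(which(pos & counts == m)[1] - 1L)
}

#' @describeIn spine_crop Lateral bounds from the anchor row: first and last
#'   white pixels, grown along contiguous white runs, padded by `pad` and
#'   clamped to the image. Returns `c(x_min, x_max)`, half-open.
#' @param row 0-based row index.
#' @param pad Padding in pixels.
#' @export
locate_lateral_bounds <- function(binary, row, pad = 50L) {
  b <- assert_binary(binary)
  if (row < 0 || row >= nrow(b)) abort("`row` outside image.")
  white <- which(b[row + 1, ] == 255L) - 1L
  if (length(white) == 0) abort("anchor row contains no white pixels.")
  a <- min(white); z <- max(white)
  rowv <- b[row + 1, ]
  while (a > 0 && rowv[a] == 255L) a <- a - 1L        # rowv[a] is pixel a-1
  while (z < ncol(b) - 1L && rowv[z + 2L] == 255L) z <- z + 1L
  c(
    x_min = as.integer(max(a - pad, 0L)),
    x_max = as.integer(min(z + 1L + pad, ncol(b)))
  )
}

#' @describeIn spine_crop Vertical bounds: smallest and largest rows with any
#'   white pixel in the column band `[x_min, x_max)`, padded by `pad` and
#'   clamped. Returns `c(y_min, y_max)`, half-open.
#' @param x_min,x_max Column band (0-based, half-open).
#' @export
locate_vertical_bounds <- function(binary, x_min, x_max, pad = 50L) {
  b <- assert_binary(binary)
  if (x_min < 0 || x_max > ncol(b) || x_min >= x_max) abort("invalid column band.")
  band_rows <- which(rowSums(b[, (x_min + 1):x_max, drop = FALSE] == 255L) > 0)
  if (length(band_rows) == 0) abort("column band contains no white pixels.")
  y_top <- min(band_rows) - 1L
  y_bot <- max(band_rows) - 1L
  c(
    y_min = as.integer(max(y_top - pad, 0L)),
    y_max = as.integer(min(y_bot + 1L + pad, nrow(b)))
  )
}

#' Crop the spine region from a radiograph
#'
#' Composes the row-scan steps: anchor-row selection, lateral bounds with
#' `pad_x`, vertical bounds with `pad_y`. Returns the crop region and the
#' cropped grayscale sub-image.
#'
#' @param image Gray image (same dimensions as `binary`).
#' @param binary Binarized image, e.g. from [binarize_pipeline()].
#' @param pad_x,pad_y Lateral and vertical padding in pixels (defaults 50).
#' @return A list with `region` (named list `x_min`, `x_max`, `y_min`,
#'   `y_max`, `pad_x`, `pad_y`, `anchor_row`; 0-based half-open) and `image`
#'   (the cropped gray image).
#' @export
crop_spine <- function(image, binary, pad_x = 50L, pad_y = 50L) {
  img <- assert_gray(image)
  b <- assert_binary(binary)
  if (!all(dim(img) == dim(b))) abort("`image` and `binary` must share dimensions.")
  anchor <- select_anchor_row(row_white_counts(b))
  lat <- locate_lateral_bounds(b, anchor, pad = pad_x)
  vert <- locate_vertical_bounds(b, lat[["x_min"]], lat[["x_max"]], pad = pad_y)
  region <- list(
    x_min = lat[["x_min"]], x_max = lat[["x_max"]],
    y_min = vert[["y_min"]], y_max = vert[["y_max"]],
    pad_x = as.integer(pad_x), pad_y = as.integer(pad_y),
    anchor_row = anchor
  )
  cropped <- img[(region$y_min + 1):region$y_max, (region$x_min + 1):region$x_max,
    drop = FALSE
  ]
  list(region = region, image = cropped)
}
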