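#' Grayscale image containers and coordinate convention
#'
#' Throughout the package a grayscale image ("gray image") is an integer
#' matrix with values in `[0, 255]`; rows are image rows (y) and columns are
#' image columns (x). A binary image is a gray image containing only the
#' values 0 (background) and 255 (foreground).
#'
#' The coordinate convention, used by every module, is: `x` = column,
#' `y` = row, origin at the top-left pixel, 0-based. Bounding boxes and crop
#' regions are half-open intervals `[x_min, x_max) x [y_min, y_max)`. So a
#' pixel `(x, y)` corresponds to matrix element `img[y + 1, x + 1]`.
#'
#' @param pixels A numeric or integer matrix.
#' @return `gray_image()` returns a validated integer matrix.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16))
#' dim(img)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels)) abort("`pixels` must be a matrix.")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) abort("image must be at least 1x1.")
  if (anyNA(pixels)) abort("image contains NA values.")
  px <- pixels
  if (!is.integer(px)) {
    if (any(abs(px - round(px)) > 1e-8)) abort("intensities must be integers.")
    storage.mode(px) <- "integer"
  }
  if (min(px) < 0L || max(px) > 255L) abort("intensities must lie in [0, 255].")
  px
}

# Validate without copying when already integer; internal fast path.
assert_gray <- function(img, arg = "image") {
  if (!is.matrix(img) || !(is.integer(img) || is.double(img))) {
    abort(sprintf("`%s` must be an integer matrix in [0, 255].", arg))
  }
  gray_image(img)
}

assert_binary <- function(img, arg = "binary") {
  img <- assert_gray(img, arg)
  if (!all(img == 0L | img == 255L)) {
    abort(sprintf("`%s` must contain only the values 0 and 255.", arg))
  }
  img
}

img_width <- function(img) ncol(img)
img_height <- function(img) nrow(img)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Read a grayscale image from disk
#'
#' Reads PNG (via the png package) or JPEG (via EBImage, if installed) into
#' the package's gray-image matrix form. RGB input is collapsed to luminance
#' (Rec. 601 weights 0.299/0.587/0.114); bit depths above 8 are rescaled
#' linearly to `[0, 255]`. DICOM is not supported by the core package and
#' raises an informative error.
#'
#' @param path Path to the image file.
#' @return An integer matrix in `[0, 255]` (see [gray_image()]).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("image file does not exist: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    tryCatch(png::readPNG(path), error = function(e) {
      abort(sprintf("unreadable PNG file %s: %s", path, conditionMessage(e)))
    })
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      abort("JPEG input requires the EBImage package.")
    }
    img <- tryCatch(EBImage::readImage(path), error = function(e) {
      abort(sprintf("unreadable JPEG file %s: %s", path, conditionMessage(e)))
    })
    a <- EBImage::imageData(img)
    # EBImage stores x as the first dimension; transpose to row = y.
    if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
  } else if (ext %in% c("dcm", "dicom")) {
    abort(sprintf(
      "DICOM input is not supported by the core package (file %s); convert to PNG first.",
      path
    ))
  } else {
    abort(sprintf("unsupported image format '%s' for %s (PNG/JPEG supported).", ext, path))
  }
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    arr <- if (nc >= 3) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  }
  if (length(arr) == 0) abort(sprintf("empty image file: %s", path))
  # readers return intensities scaled to [0,1] whatever the source bit depth
  gray_image(round(arr * 255))
}

#' Write a gray or binary image as 8-bit PNG
#'
#' @param image Gray image matrix.
#' @param path Output path (PNG).
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  image <- assert_gray(image)
  ok <- tryCatch(
    {
      png::writePNG(image / 255, target = path)
      TRUE
    },
    error = function(e) abort(sprintf("cannot write PNG to %s: %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Default detector class map
#'
#' Maps YOLO class ids to anatomical labels: 0..5 are vertebrae C2..C7 and 6
#' is the neural foramen. Override by passing a named integer vector
#' (names = labels, values = class ids) to the label I/O functions.
#'
#' @return Named integer vector.
#' @export
cspine_class_map <- function() {
  c(C2 = 0L, C3 = 1L, C4 = 2L, C5 = 3L, C6 = 4L, C7 = 5L, FORAMEN = 6L)
}

vertebra_labels <- function() c("C2", "C3", "C4", "C5", "C6", "C7")

#' Read YOLO-format annotation labels
#'
#' Parses a whitespace-delimited YOLO label file, one object per line:
#' `class x_center y_center width height`, with the four geometry fields
#' normalized to `[0, 1]`.
#'
#' @param path Path to the label text file.
#' @param n_classes Number of valid classes; `class_id` must be in
#'   `[0, n_classes)`.
#' @return A tibble with columns `class_id`, `x_center`, `y_center`,
#'   `box_width`, `box_height`, one row per non-empty line, in file order.
#' @export
read_yolo_labels <- function(path, n_classes = length(cspine_class_map())) {
  if (!file.exists(path)) abort(sprintf("label file does not exist: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  recs <- purrr::map(keep, function(i) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(parts) != 5) {
      abort(sprintf("line %d of %s: expected 5 fields, got %d.", i, path, length(parts)))
    }
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals)) abort(sprintf("line %d of %s: non-numeric field.", i, path))
    cls <- vals[1]
    if (cls != round(cls) || cls < 0 || cls >= n_classes) {
      abort(sprintf("line %d of %s: class id %s outside [0, %d).", i, path, parts[1], n_classes))
    }
    geom <- vals[2:5]
    if (any(geom < 0) || any(geom > 1)) {
      abort(sprintf("line %d of %s: geometry outside [0, 1].", i, path))
    }
    if (vals[4] <= 0 || vals[5] <= 0) {
      abort(sprintf("line %d of %s: box width/height must be positive.", i, path))
    }
    tibble(
      class_id = as.integer(cls), x_center = vals[2], y_center = vals[3],
      box_width = vals[4], box_height = vals[5]
    )
  })
  if (length(recs) == 0) {
    return(tibble(
      class_id = integer(), x_center = double(), y_center = double(),
      box_width = double(), box_height = double()
    ))
  }
  dplyr::bind_rows(recs)
}

#' Write YOLO-format annotation labels
#'
#' @param labels Tibble as returned by [read_yolo_labels()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_yolo_labels <- function(labels, path) {
  lines <- sprintf(
    "%d %.6f %.6f %.6f %.6f",
    labels$class_id, labels$x_center, labels$y_center,
    labels$box_width, labels$box_height
  )
  writeLines(lines, path)
  invisible(path)
}
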