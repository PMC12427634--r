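#' Enhance a vertebra/foramen region of interest for segmentation
#'
#' Applies percentile contrast stretching (`p_low` -> 0, `p_high` -> 255),
#' Gaussian smoothing, Otsu binarization, and morphological opening then
#' closing with a 3x3 cross, yielding a clean binary mask of the dominant
#' structure inside the ROI.
#'
#' @param roi Gray image matrix, at least 8x8.
#' @param p_low,p_high Stretch percentiles (defaults 2 and 98).
#' @param sigma Gaussian blur standard deviation (default 1).
#' @return Binary image of the same size as `roi`.
#' @export
enhance_roi <- function(roi, p_low = 2, p_high = 98, sigma = 1) {
  img <- assert_gray(roi)
  if (nrow(img) < 8 || ncol(img) < 8) abort("ROI must be at least 8x8.")
  q <- quantile(img, probs = c(p_low, p_high) / 100, names = FALSE)
  if (q[2] <= q[1]) abort("degenerate ROI: no intensity spread.")
  stretched <- img
  stretched[] <- as.integer(clamp(round((img - q[1]) / (q[2] - q[1]) * 255), 0, 255))
  smoothed <- gaussian_blur(stretched, sigma = sigma)
  t_otsu <- otsu_threshold(smoothed)
  # strictly above the (lowest-maximizing) threshold: the threshold bin
  # itself belongs to the dark class, so blur halos are excluded
  bin <- smoothed
  bin[] <- ifelse(smoothed > t_otsu, 255L, 0L)
  morph_close(morph_open(bin))
}

# Binary erosion/dilation with a 3x3 cross, edge-replicated.
shift_repl <- function(m, dy, dx) {
  ri <- clamp(seq_len(nrow(m)) + dy, 1, nrow(m))
  ci <- clamp(seq_len(ncol(m)) + dx, 1, ncol(m))
  m[ri, ci, drop = FALSE]
}

erode_cross <- function(b) {
  pmin(b, shift_repl(b, 1, 0), shift_repl(b, -1, 0), shift_repl(b, 0, 1), shift_repl(b, 0, -1))
}

dilate_cross <- function(b) {
  pmax(b, shift_repl(b, 1, 0), shift_repl(b, -1, 0), shift_repl(b, 0, 1), shift_repl(b, 0, -1))
}

morph_open <- function(b) dilate_cross(erode_cross(b))
morph_close <- function(b) erode_cross(dilate_cross(b))

#' Largest connected component of a binary image
#'
#' Extracts the maximum-area 8-connected foreground component; area ties are
#' broken toward the component whose first pixel in row-major (top-to-bottom,
#' left-to-right) order comes first.
#'
#' @param binary Binary image with at least one white pixel.
#' @param offset Length-2 integer `(x, y)` giving the position of the mask's
#'   origin in full-image coordinates (default `c(0, 0)`).
#' @return A `component_mask` list: `mask` (binary matrix containing only the
#'   component), `area` (pixel count), `offset`.
#' @export
largest_component <- function(binary, offset = c(0L, 0L)) {
  b <- assert_binary(binary)
  lab <- cpp_label_components(b)
  if (max(lab) == 0) abort("no component: image has no white pixels.")
  areas <- tabulate(lab[lab > 0])
  best <- which(areas == max(areas))
  if (length(best) > 1) {
    # labels are assigned in raster-scan order of first encounter, but
    # row-major order scans rows first; pick explicitly.
    first_rm <- purrr::map_dbl(best, function(l) {
      idx <- which(lab == l)
      y <- (idx - 1) %% nrow(lab)
      x <- (idx - 1) %/% nrow(lab)
      min(y * ncol(lab) + x)
    })
    best <- best[which.min(first_rm)]
  }
  mask <- b
  mask[] <- ifelse(lab == best, 255L, 0L)
  structure(
    list(mask = mask, area = areas[best], offset = as.numeric(offset)),
    class = "component_mask"
  )
}

mask_coords <- function(mask) {
  idx <- which(mask == 255L)
  tibble(
    x = (idx - 1) %/% nrow(mask),
    y = (idx - 1) %% nrow(mask)
  )
}

pick_extreme <- function(co, f) {
  i <- order(-f, co$y, co$x)[1]
  c(x = co$x[i], y = co$y[i])
}

#' Directional extreme points of a component
#'
#' Corner-like landmarks of the component, defined over foreground pixels by
#' the diagonal functionals: bottom-left maximizes `y - x`, bottom-right
#' maximizes `y + x`, top-left minimizes `y + x`, top-right minimizes
#' `y - x`. Ties go to the smaller `y`, then smaller `x`. Coordinates are
#' mask-local.
#'
#' @param mask A `component_mask` (or binary matrix).
#' @return List of four `(x, y)` points: `bottom_left`, `bottom_right`,
#'   `top_left`, `top_right`.
#' @export
directional_extrema <- function(mask) {
  m <- if (inherits(mask, "component_mask")) mask$mask else assert_binary(mask)
  co <- mask_coords(m)
  if (nrow(co) == 0) abort("mask has no foreground pixels.")
  list(
    bottom_left = pick_extreme(co, co$y - co$x),
    bottom_right = pick_extreme(co, co$y + co$x),
    top_left = pick_extreme(co, -(co$y + co$x)),
    top_right = pick_extreme(co, -(co$y - co$x))
  )
}

# Column of the midpoint between two x's, half-to-even; snapped to the
# nearest column that actually contains foreground.
mid_column <- function(x1, x2, cols_with_fg) {
  x <- round((x1 + x2) / 2)
  if (x %in% cols_with_fg) return(list(x = x, fallback = FALSE))
  list(x = cols_with_fg[which.min(abs(cols_with_fg - x))], fallback = TRUE)
}

#' Upper and lower reference points of a vertebral body
#'
#' From the four directional extrema, takes the x-midpoint of the two bottom
#' corners (rounded half-to-even) and intersects that column with the lower
#' white boundary to give the lower reference point; the analogous
#' construction on the top corners gives the upper reference point. If the
#' midpoint column contains no foreground (possible for concave masks) the
#' nearest foreground-bearing column is used and flagged. Points are reported
#' in full-image coordinates via the mask offset.
#'
#' @param mask A `component_mask`.
#' @return A `reference_points` list: `bottom_left`, `bottom_right`,
#'   `top_left`, `top_right`, `lower_ref`, `upper_ref` (all `(x, y)` in
#'   full-image coordinates) and `fallback` flag.
#' @export
reference_points <- function(mask) {
  stopifnot(inherits(mask, "component_mask"))
  m <- mask$mask
  ex <- directional_extrema(mask)
  co <- mask_coords(m)
  cols_fg <- sort(unique(co$x))
  lo <- mid_column(ex$bottom_left[["x"]], ex$bottom_right[["x"]], cols_fg)
  hi <- mid_column(ex$top_left[["x"]], ex$top_right[["x"]], cols_fg)
  lower_y <- max(co$y[co$x == lo$x])
  upper_y <- min(co$y[co$x == hi$x])
  off <- mask$offset
  shift <- function(p) c(x = p[["x"]] + off[1], y = p[["y"]] + off[2])
  structure(
    list(
      bottom_left = shift(ex$bottom_left), bottom_right = shift(ex$bottom_right),
      top_left = shift(ex$top_left), top_right = shift(ex$top_right),
      lower_ref = c(x = lo$x + off[1], y = lower_y + off[2]),
      upper_ref = c(x = hi$x + off[1], y = upper_y + off[2]),
      fallback = lo$fallback || hi$fallback
    ),
    class = "reference_points"
  )
}

# Same construction rotated 90 degrees: left/right boundary midpoints, used
# for the vertebra-to-foramen measurement.
lateral_reference_points <- function(mask) {
  stopifnot(inherits(mask, "component_mask"))
  m <- mask$mask
  co <- mask_coords(m)
  if (nrow(co) == 0) abort("mask has no foreground pixels.")
  pick <- function(f) {
    i <- order(-f, co$x, co$y)[1]
    c(x = co$x[i], y = co$y[i])
  }
  right_bottom <- pick(co$x + co$y)
  right_top <- pick(co$x - co$y)
  left_top <- pick(-(co$x + co$y))
  left_bottom <- pick(-(co$x - co$y))
  rows_fg <- sort(unique(co$y))
  mid_row <- function(y1, y2) {
    y <- round((y1 + y2) / 2)
    if (!(y %in% rows_fg)) y <- rows_fg[which.min(abs(rows_fg - y))]
    y
  }
  y_r <- mid_row(right_top[["y"]], right_bottom[["y"]])
  y_l <- mid_row(left_top[["y"]], left_bottom[["y"]])
  off <- mask$offset
  list(
    right_ref = c(x = max(co$x[co$y == y_r]) + off[1], y = y_r + off[2]),
    left_ref = c(x = min(co$x[co$y == y_l]) + off[1], y = y_l + off[2])
  )
}

centroid_x <- function(mask) mean(mask_coords(mask$mask)$x) + mask$offset[1]

#' Euclidean distance between two pixel points
#'
#' @param p1,p2 Length-2 numeric vectors `(x, y)`.
#' @return Non-negative distance in pixels.
#' @export
euclidean_distance <- function(p1, p2) {
  sqrt((p2[[1]] - p1[[1]])^2 + (p2[[2]] - p1[[2]])^2)
}

new_measurement <- function(kind, from_label, to_label, p1, p2) {
  tibble(
    kind = kind, from_label = from_label, to_label = to_label,
    p1_x = p1[[1]], p1_y = p1[[2]], p2_x = p2[[1]], p2_y = p2[[2]],
    distance_px = euclidean_distance(p1, p2)
  )
}

#' Intervertebral distance between two adjacent vertebrae
#'
#' Distance from the upper vertebra's lower reference point to the lower
#' vertebra's upper reference point, in full-image coordinates.
#'
#' @param upper_mask,lower_mask `component_mask`s of the two bodies.
#' @param labels Character 2-vector, e.g. `c("C2", "C3")`.
#' @return One-row measurement tibble.
#' @export
measure_intervertebral <- function(upper_mask, lower_mask, labels = c("C2", "C3")) {
  up <- reference_points(upper_mask)
  lo <- reference_points(lower_mask)
  new_measurement("intervertebral", labels[[1]], labels[[2]], up$lower_ref, lo$upper_ref)
}

#' Vertebra-to-neural-foramen distance
#'
#' Midpoint of the vertebra's foramen-facing lateral boundary to the midpoint
#' of the foramen's vertebra-facing boundary (the facing sides are determined
#' from the component centroids; by default the foramen's medial side is
#' used).
#'
#' @param vertebra_mask,foramen_mask `component_mask`s.
#' @param labels Character 2-vector `c(vertebra_label, "FORAMEN")`.
#' @param foramen_side `"facing"` (medial, default) or `"far"` (lateral).
#' @return One-row measurement tibble.
#' @export
measure_vertebra_foramen <- function(vertebra_mask, foramen_mask,
                                     labels = c("C2", "FORAMEN"),
                                     foramen_side = c("facing", "far")) {
  foramen_side <- match.arg(foramen_side)
  v <- lateral_reference_points(vertebra_mask)
  f <- lateral_reference_points(foramen_mask)
  foramen_right_of_vertebra <- centroid_x(foramen_mask) >= centroid_x(vertebra_mask)
  p_v <- if (foramen_right_of_vertebra) v$right_ref else v$left_ref
  facing <- if (foramen_right_of_vertebra) f$left_ref else f$right_ref
  far <- if (foramen_right_of_vertebra) f$right_ref else f$left_ref
  p_f <- if (foramen_side == "facing") facing else far
  new_measurement("vertebra_foramen", labels[[1]], labels[[2]], p_v, p_f)
}

#' Pipeline configuration
#'
#' @param preprocess A [preprocess_config()].
#' @param pad_x,pad_y Spine-crop padding in pixels (defaults 50).
#' @param roi_expand Fractional expansion of each detection box per side
#'   before measurement (default 0.1).
#' @param stretch_low,stretch_high,roi_sigma ROI enhancement parameters, see
#'   [enhance_roi()].
#' @param mm_per_px Optional physical pixel spacing; when given, distances
#'   are also reported in millimeters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preprocess = preprocess_config(), pad_x = 50L, pad_y = 50L,
                            roi_expand = 0.1, stretch_low = 2, stretch_high = 98,
                            roi_sigma = 1, mm_per_px = NULL) {
  stopifnot(inherits(preprocess, "preprocess_config"))
  structure(
    list(
      preprocess = preprocess, pad_x = as.integer(pad_x), pad_y = as.integer(pad_y),
      roi_expand = roi_expand, stretch_low = stretch_low, stretch_high = stretch_high,
      roi_sigma = roi_sigma, mm_per_px = mm_per_px
    ),
    class = "pipeline_config"
  )
}

expand_box <- function(d, frac, width, height) {
  wx <- (d$x_max - d$x_min) * frac
  wy <- (d$y_max - d$y_min) * frac
  list(
    x_min = as.integer(clamp(floor(d$x_min - wx), 0, width - 1)),
    x_max = as.integer(clamp(ceiling(d$x_max + wx), 1, width)),
    y_min = as.integer(clamp(floor(d$y_min - wy), 0, height - 1)),
    y_max = as.integer(clamp(ceiling(d$y_max + wy), 1, height))
  )
}

#' Run the full measurement pipeline on one radiograph
#'
#' Binarizes the image, crops the spine region, runs the detector on the
#' crop, resolves duplicate vertebra detections, pairs levels, then for each
#' detection enhances its (10%-expanded) ROI, extracts the largest connected
#' component, localizes reference points, and measures intervertebral and
#' vertebra-to-foramen distances. Failures at single levels are recorded and
#' the pipeline continues. All reported coordinates are in the frame of the
#' standardized (resized) image.
#'
#' @param image Gray image matrix.
#' @param detector A detector function, see [oracle_detector()].
#' @param config A [pipeline_config()].
#' @param image_id Identifier recorded in the report.
#' @return A [measurement_report()].
#' @export
run_pipeline <- function(image, detector, config = pipeline_config(), image_id = "image") {
  stopifnot(inherits(config, "pipeline_config"))
  img <- resize_to_standard(image, config$preprocess$target_size)
  bin <- binarize_pipeline(image, config$preprocess)
  crop <- crop_spine(img, bin, pad_x = config$pad_x, pad_y = config$pad_y)
  det <- detector(crop$image, crop$region)
  det <- resolve_duplicates(det)
  pairing <- pair_levels(det)

  w <- ncol(crop$image); h <- nrow(crop$image)
  crop_off <- c(crop$region$x_min, crop$region$y_min)
  failed <- character()
  masks <- vector("list", nrow(det))
  for (i in seq_len(nrow(det))) {
    masks[[i]] <- tryCatch(
      {
        box <- expand_box(det[i, ], config$roi_expand, w, h)
        roi <- crop$image[(box$y_min + 1):box$y_max, (box$x_min + 1):box$x_max, drop = FALSE]
        # the foramen is a radiolucent opening: invert so it segments as
        # the bright structure
        if (det$label[i] == "FORAMEN") roi <- 255L - roi
        enhanced <- enhance_roi(roi,
          p_low = config$stretch_low, p_high = config$stretch_high,
          sigma = config$roi_sigma
        )
        largest_component(enhanced, offset = c(box$x_min, box$y_min) + crop_off)
      },
      error = function(e) {
        failed <<- c(failed, det$label[i])
        NULL
      }
    )
  }

  vl <- vertebra_labels()
  mask_for <- function(lab) {
    i <- which(det$label == lab)
    if (length(i) == 0) return(NULL)
    masks[[i[1]]]
  }
  rows <- list()
  for (k in seq_len(nrow(pairing$vertebra_pairs))) {
    up_lab <- pairing$vertebra_pairs$upper[k]
    lo_lab <- pairing$vertebra_pairs$lower[k]
    up <- mask_for(up_lab); lo <- mask_for(lo_lab)
    if (is.null(up) || is.null(lo)) next
    rows[[length(rows) + 1]] <- tryCatch(
      measure_intervertebral(up, lo, labels = c(up_lab, lo_lab)),
      error = function(e) {
        failed <<- c(failed, level_pair(up_lab, lo_lab))
        NULL
      }
    )
  }
  fa <- pairing$foramen_assignment
  for (k in seq_len(nrow(fa))) {
    if (is.na(fa$vertebra[k])) next
    fmask <- masks[[fa$foramen_row[k]]]
    vmask <- mask_for(fa$vertebra[k])
    if (is.null(fmask) || is.null(vmask)) next
    rows[[length(rows) + 1]] <- tryCatch(
      measure_vertebra_foramen(vmask, fmask, labels = c(fa$vertebra[k], "FORAMEN")),
      error = function(e) NULL
    )
  }
  measurements <- if (length(rows) == 0) empty_measurements() else dplyr::bind_rows(rows)
  if (!is.null(config$mm_per_px) && nrow(measurements) > 0) {
    measurements$distance_mm <- measurements$distance_px * config$mm_per_px
  }
  missing <- sort(unique(c(setdiff(vl, det$label), failed)))
  measurement_report(
    image_id = image_id, measurements = measurements, missing_levels = missing,
    provenance = list(
      pad_x = config$pad_x, pad_y = config$pad_y, roi_expand = config$roi_expand,
      target_size = config$preprocess$target_size,
      median_window = config$preprocess$median_window,
      clahe_clip = config$preprocess$clahe_clip,
      clahe_tiles = config$preprocess$clahe_tiles,
      adaptive_block = config$preprocess$adaptive_block,
      adaptive_offset = config$preprocess$adaptive_offset,
      crop_region = crop$region
    )
  )
}
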