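#' Detection tables
#'
#' A detection is a labeled bounding box with a confidence score. Detections
#' are kept in a tibble with columns `label` (one of C2..C7 or FORAMEN),
#' `x_min`, `y_min`, `x_max`, `y_max` (pixels, 0-based half-open) and
#' `confidence` in `[0, 1]`.
#'
#' @param label Character vector of labels.
#' @param x_min,y_min,x_max,y_max Box coordinates.
#' @param confidence Confidence scores in `[0, 1]`.
#' @return A detection tibble.
#' @export
detections <- function(label = character(), x_min = double(), y_min = double(),
                       x_max = double(), y_max = double(), confidence = double()) {
  d <- tibble(
    label = as.character(label), x_min = as.numeric(x_min),
    y_min = as.numeric(y_min), x_max = as.numeric(x_max),
    y_max = as.numeric(y_max), confidence = as.numeric(confidence)
  )
  bad <- setdiff(d$label, c(vertebra_labels(), "FORAMEN"))
  if (length(bad) > 0) abort(sprintf("unknown labels: %s", paste(bad, collapse = ", ")))
  if (nrow(d) > 0 && (any(d$confidence < 0) || any(d$confidence > 1))) {
    abort("confidence must lie in [0, 1].")
  }
  if (nrow(d) > 0 && (any(d$x_max <= d$x_min) || any(d$y_max <= d$y_min))) {
    abort("boxes must have positive width and height.")
  }
  d
}

#' Convert YOLO annotation records to pixel detections
#'
#' Denormalizes YOLO-format boxes (fractions of the image) to pixel
#' coordinates for an image of the given size, mapping class ids to labels
#' through `class_map`. Confidence is fixed at 1 (annotations are treated as
#' ground truth).
#'
#' @param labels Tibble from [read_yolo_labels()].
#' @param width,height Image dimensions in pixels.
#' @param class_map Named integer vector, see [cspine_class_map()].
#' @return Detection tibble.
#' @export
labels_to_detections <- function(labels, width, height, class_map = cspine_class_map()) {
  if (nrow(labels) == 0) return(detections())
  lut <- stats::setNames(names(class_map), as.character(class_map))
  lab <- lut[as.character(labels$class_id)]
  if (anyNA(lab)) abort("class id not present in `class_map`.")
  detections(
    label = unname(lab),
    x_min = clamp((labels$x_center - labels$box_width / 2) * width, 0, width),
    y_min = clamp((labels$y_center - labels$box_height / 2) * height, 0, height),
    x_max = clamp((labels$x_center + labels$box_width / 2) * width, 0, width),
    y_max = clamp((labels$y_center + labels$box_height / 2) * height, 0, height),
    confidence = 1
  )
}

#' Detector backends
#'
#' A detector is a function `f(image, region)` returning a detection tibble
#' in the coordinate frame of `image`; `region` (a crop region from
#' [crop_spine()], or `NULL`) tells the backend where `image` sits in the
#' original radiograph frame.
#'
#' `oracle_detector()` wraps phantom ground truth (see [generate_phantom()])
#' and returns its boxes, translated into the crop frame; it is the
#' noise-free stand-in for a trained vertebra/foramen localization network.
#' `labels_detector()` wraps a YOLO annotation file or tibble expressed in
#' the original-image frame.
#'
#' @param truth Phantom ground truth (from [generate_phantom()]) or a
#'   detection tibble in original-frame pixel coordinates.
#' @return A detector function.
#' @export
oracle_detector <- function(truth) {
  boxes <- if (inherits(truth, "phantom_truth")) truth$boxes else truth
  force(boxes)
  function(image, region = NULL) {
    translate_to_frame(
      detections(
        label = boxes$label, x_min = boxes$x_min, y_min = boxes$y_min,
        x_max = boxes$x_max, y_max = boxes$y_max, confidence = 1
      ),
      image, region
    )
  }
}

#' @rdname oracle_detector
#' @param labels Path to a YOLO label file, or a tibble from
#'   [read_yolo_labels()].
#' @param width,height Original image dimensions the labels refer to.
#' @param class_map Named integer vector, see [cspine_class_map()].
#' @export
labels_detector <- function(labels, width, height, class_map = cspine_class_map()) {
  if (is.character(labels)) labels <- read_yolo_labels(labels, n_classes = length(class_map))
  det <- labels_to_detections(labels, width, height, class_map)
  function(image, region = NULL) translate_to_frame(det, image, region)
}

# Shift original-frame detections into the crop frame and clip to the image;
# boxes that end up degenerate are dropped.
translate_to_frame <- function(det, image, region) {
  if (nrow(det) == 0) return(det)
  dx <- if (is.null(region)) 0 else region$x_min
  dy <- if (is.null(region)) 0 else region$y_min
  w <- ncol(image); h <- nrow(image)
  out <- dplyr::mutate(det,
    x_min = clamp(.data$x_min - dx, 0, w), x_max = clamp(.data$x_max - dx, 0, w),
    y_min = clamp(.data$y_min - dy, 0, h), y_max = clamp(.data$y_max - dy, 0, h)
  )
  dplyr::filter(out, .data$x_max > .data$x_min, .data$y_max > .data$y_min)
}

#' Resolve duplicate vertebra detections
#'
#' For each vertebra label, only the highest-confidence detection is kept
#' (ties broken toward the larger box area, then the earlier row). FORAMEN
#' detections are all retained. Idempotent.
#'
#' @param det Detection tibble.
#' @return Detection tibble with at most one row per vertebra label.
#' @export
resolve_duplicates <- function(det) {
  if (nrow(det) == 0) return(det)
  area <- (det$x_max - det$x_min) * (det$y_max - det$y_min)
  keep <- rep(TRUE, nrow(det))
  for (lab in intersect(vertebra_labels(), det$label)) {
    idx <- which(det$label == lab)
    if (length(idx) > 1) {
      best <- idx[order(-det$confidence[idx], -area[idx], idx)[1]]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  det[keep, ]
}

#' Pair detections into measurable levels
#'
#' Builds the ordered adjacent vertebra pairs (C2-C3 ... C6-C7) among the
#' detected labels, and assigns every FORAMEN detection to the vertebra whose
#' box center is nearest its own (unassigned if no vertebra was detected).
#' Duplicates must have been resolved first.
#'
#' @param det Detection tibble (one row per vertebra label at most).
#' @return A `level_pairing` list with `vertebra_pairs`
#'   (tibble `upper`, `lower`) and `foramen_assignment`
#'   (tibble `foramen_row`, `vertebra`).
#' @export
pair_levels <- function(det) {
  vl <- vertebra_labels()
  present <- det$label[det$label %in% vl]
  if (anyDuplicated(present)) abort("resolve duplicates before pairing.")
  pairs <- tibble(upper = vl[-length(vl)], lower = vl[-1])
  pairs <- pairs[pairs$upper %in% present & pairs$lower %in% present, ]
  fidx <- which(det$label == "FORAMEN")
  vidx <- which(det$label %in% vl)
  cx <- (det$x_min + det$x_max) / 2
  cy <- (det$y_min + det$y_max) / 2
  assignment <- purrr::map_chr(fidx, function(i) {
    if (length(vidx) == 0) return(NA_character_)
    d2 <- (cx[vidx] - cx[i])^2 + (cy[vidx] - cy[i])^2
    det$label[vidx[which.min(d2)]]
  })
  structure(
    list(
      vertebra_pairs = pairs,
      foramen_assignment = tibble(foramen_row = fidx, vertebra = assignment)
    ),
    class = "level_pairing"
  )
}
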