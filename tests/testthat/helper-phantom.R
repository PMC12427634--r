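# Shared helpers for phantom-based tests.

# Ground-truth distances of a phantom as a measurement_report, so pipeline
# output can be compared via agreement_report().
truth_report <- function(truth, image_id) {
  iv <- truth$intervertebral_distances
  vf <- truth$vertebra_foramen_distances
  m <- dplyr::bind_rows(
    tibble::tibble(
      kind = "intervertebral", from_label = iv$upper, to_label = iv$lower,
      p1_x = iv$p1_x, p1_y = iv$p1_y, p2_x = iv$p2_x, p2_y = iv$p2_y,
      distance_px = iv$distance_px
    ),
    tibble::tibble(
      kind = "vertebra_foramen", from_label = vf$vertebra, to_label = "FORAMEN",
      p1_x = vf$p1_x, p1_y = vf$p1_y, p2_x = vf$p2_x, p2_y = vf$p2_y,
      distance_px = vf$distance_px
    )
  )
  measurement_report(image_id, m)
}

# Do all six ground-truth vertebra boxes fall inside the crop region?
crop_contains_truth <- function(phantom) {
  bin <- binarize_pipeline(phantom$image)
  cr <- crop_spine(phantom$image, bin)$region
  vb <- phantom$truth$boxes[phantom$truth$boxes$label != "FORAMEN", ]
  all(vb$x_min >= cr$x_min & vb$x_max <= cr$x_max &
    vb$y_min >= cr$y_min & vb$y_max <= cr$y_max)
}

# Absolute intervertebral-distance errors of a pipeline run vs ground truth.
intervertebral_errors <- function(phantom, report) {
  m <- report$measurements
  m <- m[m$kind == "intervertebral", ]
  iv <- merge(m, phantom$truth$intervertebral_distances,
    by.x = c("from_label", "to_label"), by.y = c("upper", "lower")
  )
  abs(iv$distance_px.x - iv$distance_px.y)
}

# A component_mask for a filled axis-aligned rectangle, 0-based half-open.
rect_mask <- function(x0, x1, y0, y1, h = 64, w = 64, offset = c(0, 0)) {
  m <- matrix(0L, h, w)
  m[(y0 + 1):y1, (x0 + 1):x1] <- 255L
  largest_component(m, offset = offset)
}
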