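#' Intersection-over-union of two half-open boxes
#'
#' @param a,b Lists or one-row data frames with `x_min`, `y_min`, `x_max`,
#'   `y_max`.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x_max, b$x_max) - max(a$x_min, b$x_min))
  iy <- max(0, min(a$y_max, b$y_max) - max(a$y_min, b$y_min))
  inter <- ix * iy
  union <- (a$x_max - a$x_min) * (a$y_max - a$y_min) +
    (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Match detections against ground truth
#'
#' Greedy matching by descending confidence within each class: a prediction
#' is a true positive iff its label matches and its IoU with a not-yet
#' matched truth box is at least `iou_threshold` (the best such truth is
#' consumed). Unmatched predictions are false positives; unmatched truths
#' are false negatives. True negatives are undefined in the detection
#' setting and fixed at 0.
#'
#' @param predictions Detection tibble.
#' @param truths Tibble of ground-truth boxes with `label`, `x_min`,
#'   `y_min`, `x_max`, `y_max`.
#' @param iou_threshold IoU needed for a correct localization, in `(0, 1]`
#'   (default 0.5).
#' @return Tibble with one row per label occurring in either input:
#'   `label`, `tp`, `fp`, `fn`, `tn`; attribute `"scored"` holds the
#'   per-prediction tibble (`label`, `confidence`, `is_tp`) used for
#'   average-precision computation.
#' @export
match_detections <- function(predictions, truths, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1) abort("`iou_threshold` must be in (0, 1].")
  labs <- sort(unique(c(predictions$label, truths$label)))
  scored_all <- list()
  counts <- purrr::map(labs, function(lab) {
    p <- predictions[predictions$label == lab, , drop = FALSE]
    tr <- truths[truths$label == lab, , drop = FALSE]
    ord <- order(-p$confidence)
    used <- rep(FALSE, nrow(tr))
    is_tp <- rep(FALSE, nrow(p))
    for (i in ord) {
      if (nrow(tr) == 0) break
      ious <- purrr::map_dbl(seq_len(nrow(tr)), function(j) box_iou(p[i, ], tr[j, ]))
      ious[used] <- -1
      j <- which.max(ious)
      if (length(j) == 1 && ious[j] >= iou_threshold) {
        used[j] <- TRUE
        is_tp[i] <- TRUE
      }
    }
    scored_all[[lab]] <<- tibble(
      label = rep(lab, nrow(p)), confidence = p$confidence, is_tp = is_tp
    )
    tibble(
      label = lab, tp = sum(is_tp), fp = sum(!is_tp),
      fn = sum(!used), tn = 0L
    )
  })
  out <- dplyr::bind_rows(counts)
  attr(out, "scored") <- dplyr::bind_rows(scored_all)
  attr(out, "n_truth") <- stats::setNames(
    purrr::map_int(labs, ~ sum(truths$label == .x)), labs
  )
  out
}

#' Accuracy, precision and recall from confusion counts
#'
#' `accuracy = (tp + tn) / (tp + fp + tn + fn)`, `precision = tp / (tp + fp)`,
#' `recall = tp / (tp + fn)`. A rate whose denominator is zero is undefined
#' and reported as `NA`, not 0.
#'
#' @param counts Tibble or list with `tp`, `fp`, `fn`, `tn` (vectorized).
#' @return Tibble with columns `accuracy`, `precision`, `recall` (plus
#'   `label` when present in the input).
#' @export
rates <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (any(c(tp, fp, fn, tn) < 0)) abort("confusion counts must be non-negative.")
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- tibble(
    accuracy = safe_div(tp + tn, tp + fp + tn + fn),
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn)
  )
  if (!is.null(counts$label)) out <- dplyr::bind_cols(tibble(label = counts$label), out)
  out
}

#' Average precision of a scored detection ranking
#'
#' All-points interpolation: predictions are sorted by descending confidence,
#' cumulative precision/recall are accumulated, precision is replaced by its
#' running maximum from the right, and AP is the area under the resulting
#' precision-recall staircase.
#'
#' @param scored Tibble with `confidence` and logical `is_tp` (one row per
#'   prediction).
#' @param n_truth Number of ground-truth objects (>= 1).
#' @return A `pr_curve` list: `curve` (tibble `recall`, `precision` ordered
#'   by descending confidence) and `ap`.
#' @export
average_precision <- function(scored, n_truth) {
  if (n_truth < 1) abort("`n_truth` must be at least 1.")
  if (nrow(scored) == 0) {
    return(structure(list(curve = tibble(recall = double(), precision = double()), ap = 0),
      class = "pr_curve"
    ))
  }
  ord <- order(-scored$confidence)
  tp <- cumsum(scored$is_tp[ord])
  fp <- cumsum(!scored$is_tp[ord])
  recall <- tp / n_truth
  precision <- tp / (tp + fp)
  p_interp <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * p_interp)
  structure(
    list(curve = tibble(recall = recall, precision = precision), ap = ap),
    class = "pr_curve"
  )
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> AP = %.4f over %d predictions\n", x$ap, nrow(x$curve)))
  invisible(x)
}

#' Mean average precision over classes
#'
#' Arithmetic mean of the defined per-class AP values; classes with
#' undefined AP (`NA`) are skipped. Errors if none is defined.
#'
#' @param aps Numeric vector of per-class APs, or a list of `pr_curve`s.
#' @return mAP as a single number.
#' @export
mean_ap <- function(aps) {
  if (is.list(aps) && !is.numeric(aps)) {
    aps <- purrr::map_dbl(aps, function(a) if (inherits(a, "pr_curve")) a$ap else as.numeric(a))
  }
  ok <- !is.na(aps)
  if (!any(ok)) abort("no class has a defined average precision.")
  mean(aps[ok])
}

#' Pearson product-moment correlation coefficient
#'
#' Standard Pearson correlation of paired values; errors on unequal lengths,
#' fewer than two pairs, or a constant vector (undefined correlation).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
ppmcc <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal lengths.")
  if (length(x) < 2) abort("need at least two pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("undefined: constant vector.")
  stats::cor(x, y)
}

#' Agreement between two sets of distance measurements
#'
#' Pairs the distances of a system report set against a reference set by
#' case, kind and level pair, and computes the Pearson correlation per case
#' and kind, plus the across-case average per kind — the layout used to
#' compare automated and clinician measurements.
#'
#' @param system,reference Lists of [measurement_report()]s (cases matched
#'   by `image_id`), or tidy measurement tibbles containing `image_id`,
#'   `kind`, `from_label`, `to_label`, `distance_px`.
#' @return Tibble with columns `case`, `kind`, `ppmcc`, `n_pairs`; the
#'   summary rows have `case == "average"`. Kinds with fewer than two common
#'   pairs in a case get `NA`.
#' @export
agreement_report <- function(system, reference) {
  as_meas_tbl <- function(r) {
    if (inherits(r, "measurement_report")) return(tidy(r))
    if (is.list(r) && !is.data.frame(r)) return(dplyr::bind_rows(purrr::map(r, tidy)))
    as_tibble(r)
  }
  s <- as_meas_tbl(system)
  r <- as_meas_tbl(reference)
  joined <- dplyr::inner_join(
    dplyr::select(s, "image_id", "kind", "from_label", "to_label", sys_d = "distance_px"),
    dplyr::select(r, "image_id", "kind", "from_label", "to_label", ref_d = "distance_px"),
    by = c("image_id", "kind", "from_label", "to_label")
  )
  if (nrow(joined) == 0) abort("no common (case, kind, level) measurements.")
  per_case <- joined %>%
    dplyr::group_by(case = .data$image_id, kind = .data$kind) %>%
    dplyr::summarise(
      ppmcc = if (dplyr::n() >= 2 && stats::sd(.data$sys_d) > 0 && stats::sd(.data$ref_d) > 0) {
        stats::cor(.data$sys_d, .data$ref_d)
      } else {
        NA_real_
      },
      n_pairs = dplyr::n(), .groups = "drop"
    )
  avg <- per_case %>%
    dplyr::group_by(.data$kind) %>%
    dplyr::summarise(
      case = "average", ppmcc = mean(.data$ppmcc, na.rm = TRUE),
      n_pairs = sum(.data$n_pairs), .groups = "drop"
    ) %>%
    dplyr::select("case", "kind", "ppmcc", "n_pairs")
  dplyr::bind_rows(per_case, avg)
}

#' Evaluate a detector against phantom ground truth
#'
#' Convenience wrapper: matches predictions to truths at the given IoU
#' threshold and returns per-class counts, rates, per-class PR curves and
#' the mAP.
#'
#' @inheritParams match_detections
#' @return List with `counts`, `rates`, `curves` (named list of
#'   `pr_curve`s), `map`.
#' @export
evaluate_detections <- function(predictions, truths, iou_threshold = 0.5) {
  counts <- match_detections(predictions, truths, iou_threshold)
  scored <- attr(counts, "scored")
  n_truth <- attr(counts, "n_truth")
  curves <- purrr::map(
    stats::setNames(counts$label, counts$label),
    function(lab) {
      nt <- n_truth[[lab]]
      if (is.na(nt) || nt < 1) return(NULL)
      average_precision(scored[scored$label == lab, , drop = FALSE], nt)
    }
  )
  curves <- purrr::compact(curves)
  aps <- purrr::map_dbl(curves, "ap")
  list(counts = counts, rates = rates(counts), curves = curves, map = mean_ap(aps))
}
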