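#' Measurement reports
#'
#' A measurement report bundles the distances measured on one radiograph:
#' `image_id`, a tibble of measurements (one row per distance), the vertebra
#' levels that could not be measured, and a provenance snapshot of the
#' configuration used. Distances are in pixels; if a `mm_per_px` scale was
#' supplied a `distance_mm` column is added.
#'
#' @param image_id Identifier of the source image.
#' @param measurements Tibble with columns `kind` (`"intervertebral"` or
#'   `"vertebra_foramen"`), `from_label`, `to_label`, `p1_x`, `p1_y`,
#'   `p2_x`, `p2_y`, `distance_px`.
#' @param missing_levels Character vector of undetected/failed levels.
#' @param provenance Named list describing the configuration.
#' @return An object of class `measurement_report`.
#' @export
measurement_report <- function(image_id, measurements = empty_measurements(),
                               missing_levels = character(), provenance = list()) {
  measurements <- as_tibble(measurements)
  needed <- c("kind", "from_label", "to_label", "p1_x", "p1_y", "p2_x", "p2_y", "distance_px")
  missing_cols <- setdiff(needed, names(measurements))
  if (length(missing_cols) > 0) {
    abort(sprintf("measurements lack columns: %s", paste(missing_cols, collapse = ", ")))
  }
  iv <- measurements[measurements$kind == "intervertebral", ]
  if (anyDuplicated(paste(iv$from_label, iv$to_label))) {
    abort("at most one intervertebral measurement per adjacent pair.")
  }
  structure(
    list(
      image_id = as.character(image_id), measurements = measurements,
      missing_levels = as.character(missing_levels), provenance = provenance
    ),
    class = "measurement_report"
  )
}

#' @rdname measurement_report
#' @export
empty_measurements <- function() {
  tibble(
    kind = character(), from_label = character(), to_label = character(),
    p1_x = double(), p1_y = double(), p2_x = double(), p2_y = double(),
    distance_px = double()
  )
}

#' @export
print.measurement_report <- function(x, ...) {
  cat(sprintf(
    "<measurement_report> image '%s': %d measurement(s), %d missing level(s)\n",
    x$image_id, nrow(x$measurements), length(x$missing_levels)
  ))
  if (nrow(x$measurements) > 0) print(x$measurements)
  if (length(x$missing_levels) > 0) {
    cat("missing:", paste(x$missing_levels, collapse = ", "), "\n")
  }
  invisible(x)
}

level_pair <- function(from, to) paste0(from, "-", to)

#' Write / read a measurement report
#'
#' CSV output has one row per measurement with columns `image_id`, `kind`,
#' `level_pair`, `distance_px` plus the two endpoint coordinates; JSON output
#' mirrors the full report (including missing levels and provenance). Values
#' round-trip to at least six decimal places.
#'
#' @param report A [measurement_report()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "measurement_report"))
  if (format == "csv") {
    m <- report$measurements
    out <- tibble(
      image_id = rep(report$image_id, nrow(m)),
      kind = m$kind,
      level_pair = level_pair(m$from_label, m$to_label),
      distance_px = m$distance_px,
      p1_x = m$p1_x, p1_y = m$p1_y, p2_x = m$p2_x, p2_y = m$p2_y
    )
    tryCatch(readr::write_csv(out, path),
      error = function(e) abort(sprintf("cannot write report to %s: %s", path, conditionMessage(e)))
    )
  } else {
    payload <- list(
      image_id = report$image_id,
      measurements = report$measurements,
      missing_levels = report$missing_levels,
      provenance = report$provenance
    )
    tryCatch(
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null"),
      error = function(e) abort(sprintf("cannot write report to %s: %s", path, conditionMessage(e)))
    )
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    d <- readr::read_csv(path, show_col_types = FALSE)
    if (nrow(d) == 0) {
      return(measurement_report(image_id = NA_character_))
    }
    parts <- strsplit(d$level_pair, "-", fixed = TRUE)
    m <- tibble(
      kind = d$kind,
      from_label = purrr::map_chr(parts, 1),
      to_label = purrr::map_chr(parts, 2),
      p1_x = d$p1_x, p1_y = d$p1_y, p2_x = d$p2_x, p2_y = d$p2_y,
      distance_px = d$distance_px
    )
    measurement_report(image_id = d$image_id[[1]], measurements = m)
  } else {
    p <- jsonlite::read_json(path, simplifyVector = TRUE)
    m <- if (length(p$measurements) == 0) empty_measurements() else as_tibble(p$measurements)
    measurement_report(
      image_id = p$image_id, measurements = m,
      missing_levels = unlist(p$missing_levels),
      provenance = as.list(p$provenance)
    )
  }
}

#' Tidy methods for measurement reports
#'
#' `tidy()` returns the per-measurement tibble (with `image_id` and
#' `level_pair` columns added); `glance()` returns a one-row summary.
#'
#' @param x A `measurement_report`.
#' @param ... Unused.
#' @method tidy measurement_report
#' @export
tidy.measurement_report <- function(x, ...) {
  m <- x$measurements
  dplyr::mutate(m,
    image_id = x$image_id,
    level_pair = level_pair(m$from_label, m$to_label),
    .before = 1
  )
}

#' @rdname tidy.measurement_report
#' @method glance measurement_report
#' @export
glance.measurement_report <- function(x, ...) {
  m <- x$measurements
  iv <- m$distance_px[m$kind == "intervertebral"]
  vf <- m$distance_px[m$kind == "vertebra_foramen"]
  tibble(
    image_id = x$image_id,
    n_measurements = nrow(m),
    n_intervertebral = length(iv),
    n_vertebra_foramen = length(vf),
    mean_intervertebral_px = if (length(iv)) mean(iv) else NA_real_,
    mean_vertebra_foramen_px = if (length(vf)) mean(vf) else NA_real_,
    n_missing_levels = length(x$missing_levels)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
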