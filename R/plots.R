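#' Plot a measurement report
#'
#' Bar chart of measured distances per level pair, split by measurement
#' kind.
#'
#' @param object A [measurement_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot measurement_report
#' @export
autoplot.measurement_report <- function(object, ...) {
  d <- tidy(object)
  if (nrow(d) == 0) abort("report contains no measurements to plot.")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level_pair, y = .data$distance_px)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$kind), scales = "free_x") +
    ggplot2::labs(
      x = NULL, y = "distance (px)",
      title = sprintf("Distance measurements: %s", object$image_id)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param object A `pr_curve` from [average_precision()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "recall", y = "precision",
      title = sprintf("Precision-recall (AP = %.3f)", object$ap)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an image with detections and measurements
#'
#' Renders the grayscale raster with detection boxes and measurement
#' segments layered on top.
#'
#' @param image Gray image matrix.
#' @param detections Optional detection tibble.
#' @param measurements Optional [measurement_report()] or measurement tibble.
#' @return A ggplot object.
#' @export
plot_radiograph <- function(image, detections = NULL, measurements = NULL) {
  img <- assert_gray(image)
  h <- nrow(img); w <- ncol(img)
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(
      grDevices::as.raster(img / 255),
      xmin = 0, xmax = w, ymin = -h, ymax = 0
    ) +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(-h, 0), expand = FALSE) +
    ggplot2::theme_void()
  if (!is.null(detections) && nrow(detections) > 0) {
    p <- p + ggplot2::geom_rect(
      data = detections,
      ggplot2::aes(
        xmin = .data$x_min, xmax = .data$x_max,
        ymin = -.data$y_max, ymax = -.data$y_min
      ),
      fill = NA, colour = "yellow", linewidth = 0.4
    ) +
      ggplot2::geom_text(
        data = detections,
        ggplot2::aes(
          x = .data$x_min, y = -.data$y_min,
          label = sprintf("%s %.2f", .data$label, .data$confidence)
        ),
        colour = "yellow", hjust = 0, vjust = -0.3, size = 2.6
      )
  }
  m <- measurements
  if (inherits(m, "measurement_report")) m <- m$measurements
  if (!is.null(m) && nrow(m) > 0) {
    p <- p + ggplot2::geom_segment(
      data = m,
      ggplot2::aes(
        x = .data$p1_x, y = -.data$p1_y, xend = .data$p2_x, yend = -.data$p2_y,
        colour = .data$kind
      ),
      linewidth = 0.5
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
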