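#' Phantom specification
#'
#' Parameters of the synthetic lateral cervical-spine phantom: `n_vertebrae`
#' bright, individually tilted rounded-rectangle vertebral bodies (labeled
#' C2 downward) stacked along a mildly curved (lordotic) axis with known
#' gaps, one posterior radiolucent ellipse per level as the neural-foramen
#' region, a soft-tissue band, a smooth illumination gradient, and additive
#' Gaussian plus salt-and-pepper noise. All geometric ground truth is
#' computed analytically from the pre-noise geometry.
#'
#' @param image_size Square image side in pixels (default 512).
#' @param n_vertebrae Number of bodies, at least 2 (default 6 = C2..C7).
#' @param body_width,body_height Sampling ranges in pixels.
#' @param gap_range Range of inter-body gaps in pixels (default `c(5, 25)`).
#' @param tilt_range Body tilt range in degrees (default `c(-10, 10)`).
#' @param foramen_offset Range of the horizontal gap between a body's right
#'   edge and its foramen ellipse, in pixels.
#' @param foramen_semiaxes Ellipse semi-axes `(a, b)` in pixels.
#' @param intensity Named levels `background`, `soft_tissue`, `bone`,
#'   `foramen` (defaults 40/100/190/55).
#' @param gaussian_noise_sigma Additive Gaussian noise SD (default 6).
#' @param salt_pepper_fraction Fraction of impulse-noise pixels (default 0.002).
#' @param illumination_gradient_amplitude Peak-to-center amplitude of the
#'   smooth illumination plane (default 20).
#' @param curvature_amplitude Maximum quadratic x-offset of body centers
#'   modeling lordosis (default 15).
#' @param corner_radius Rounded-corner radius of the bodies (default 6).
#' @param seed Optional integer seed; identical seeds give identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 512L, n_vertebrae = 6L,
                         body_width = c(85, 115), body_height = c(42, 56),
                         gap_range = c(5, 25), tilt_range = c(-10, 10),
                         foramen_offset = c(20, 32), foramen_semiaxes = c(11, 8),
                         intensity = c(background = 40, soft_tissue = 100, bone = 190, foramen = 55),
                         gaussian_noise_sigma = 6, salt_pepper_fraction = 0.002,
                         illumination_gradient_amplitude = 20,
                         curvature_amplitude = 15, corner_radius = 6, seed = NULL) {
  if (n_vertebrae < 2) abort("`n_vertebrae` must be at least 2.")
  if (any(gap_range <= 0)) abort("`gap_range` must be positive.")
  if (!(intensity[["bone"]] > intensity[["soft_tissue"]] &&
    intensity[["soft_tissue"]] > intensity[["background"]])) {
    abort("intensities must satisfy bone > soft_tissue > background.")
  }
  structure(
    list(
      image_size = as.integer(image_size), n_vertebrae = as.integer(n_vertebrae),
      body_width = body_width, body_height = body_height, gap_range = gap_range,
      tilt_range = tilt_range, foramen_offset = foramen_offset,
      foramen_semiaxes = foramen_semiaxes, intensity = intensity,
      gaussian_noise_sigma = gaussian_noise_sigma,
      salt_pepper_fraction = salt_pepper_fraction,
      illumination_gradient_amplitude = illumination_gradient_amplitude,
      curvature_amplitude = curvature_amplitude, corner_radius = corner_radius,
      seed = seed
    ),
    class = "phantom_spec"
  )
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

# Fill a rotated rounded rectangle (center c, width w, height h, tilt theta
# radians, corner radius r) into matrix `img` with `value`; returns the
# logical fill mask as attribute-free side product.
fill_round_rect <- function(img, xc, yc, w, h, theta, r, value) {
  half_diag <- sqrt(w^2 + h^2) / 2 + 1
  x0 <- max(floor(xc - half_diag), 0); x1 <- min(ceiling(xc + half_diag), ncol(img) - 1)
  y0 <- max(floor(yc - half_diag), 0); y1 <- min(ceiling(yc + half_diag), nrow(img) - 1)
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(rep(xs, each = length(ys)), nrow = length(ys)) - xc
  Y <- matrix(rep(ys, times = length(xs)), nrow = length(ys)) - yc
  u <- cos(theta) * X + sin(theta) * Y
  v <- -sin(theta) * X + cos(theta) * Y
  du <- abs(u) - (w / 2 - r)
  dv <- abs(v) - (h / 2 - r)
  inside <- sqrt(pmax(du, 0)^2 + pmax(dv, 0)^2) <= r & abs(u) <= w / 2 & abs(v) <= h / 2
  sub <- img[ys + 1, xs + 1, drop = FALSE]
  sub[inside] <- value
  img[ys + 1, xs + 1] <- sub
  img
}

fill_ellipse <- function(img, xc, yc, a, b, value) {
  x0 <- max(floor(xc - a), 0); x1 <- min(ceiling(xc + a), ncol(img) - 1)
  y0 <- max(floor(yc - b), 0); y1 <- min(ceiling(yc + b), nrow(img) - 1)
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  Y <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  inside <- ((X - xc) / a)^2 + ((Y - yc) / b)^2 <= 1
  sub <- img[ys + 1, xs + 1, drop = FALSE]
  sub[inside] <- value
  img[ys + 1, xs + 1] <- sub
  img
}

#' Generate a synthetic cervical-spine phantom with analytic ground truth
#'
#' Renders the phantom described by `spec` and returns the image together
#' with ground truth computed from the exact pre-noise geometry: per-label
#' bounding boxes, analytic upper/lower edge-midpoint reference points,
#' foramen centers, intervertebral and vertebra-to-foramen distances, and
#' the exact binary body mask. Identical seeds produce identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list `image` (gray image) and `truth` (`phantom_truth` list).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) withr::local_seed(spec$seed)
  n <- spec$n_vertebrae
  size <- spec$image_size
  labels <- if (n == 6) vertebra_labels() else paste0("V", seq_len(n))

  w_k <- stats::runif(n, spec$body_width[1], spec$body_width[2])
  h_k <- stats::runif(n, spec$body_height[1], spec$body_height[2])
  # endplates rotate smoothly through the lordotic curve: tilts interpolate
  # between two sampled endpoint angles with small per-body jitter, so
  # adjacent bodies stay near-parallel as real vertebrae do
  t_ends <- stats::runif(2, spec$tilt_range[1], spec$tilt_range[2])
  theta_k <- seq(t_ends[1], t_ends[2], length.out = n) + stats::runif(n, -1.5, 1.5)
  theta_k <- clamp(theta_k, spec$tilt_range[1], spec$tilt_range[2]) * pi / 180
  g_k <- stats::runif(n - 1, spec$gap_range[1], spec$gap_range[2])
  f_off <- stats::runif(n, spec$foramen_offset[1], spec$foramen_offset[2])

  t_k <- if (n > 1) 2 * (seq_len(n) - 1) / (n - 1) - 1 else 0
  x_c <- size / 2 - 20 + spec$curvature_amplitude * (1 - t_k^2)

  # vertical layout: centers chained so the vertical spacing between facing
  # edge midpoints equals the sampled gap, then widened where tilted
  # endplates would leave less than `min_sep` of physical separation
  step <- h_k[-n] / 2 * cos(theta_k[-n]) + g_k + h_k[-1] / 2 * cos(theta_k[-1])
  min_sep <- 3
  y_c <- numeric(n)
  for (k in seq_len(n - 1)) {
    # facing-edge separation as a linear function of x over the horizontal
    # overlap of the two edges; evaluated at the overlap endpoints
    lower_edge <- function(x) {
      (h_k[k] / 2) * cos(theta_k[k]) +
        (x - x_c[k] + (h_k[k] / 2) * sin(theta_k[k])) * tan(theta_k[k])
    }
    upper_edge <- function(x, yrel) {
      yrel - (h_k[k + 1] / 2) * cos(theta_k[k + 1]) +
        (x - x_c[k + 1] - (h_k[k + 1] / 2) * sin(theta_k[k + 1])) * tan(theta_k[k + 1])
    }
    xl <- max(x_c[k] - w_k[k] / 2, x_c[k + 1] - w_k[k + 1] / 2)
    xr <- min(x_c[k] + w_k[k] / 2, x_c[k + 1] + w_k[k + 1] / 2)
    if (xl < xr) {
      sep <- min(
        upper_edge(xl, step[k]) - lower_edge(xl),
        upper_edge(xr, step[k]) - lower_edge(xr)
      )
      if (sep < min_sep) step[k] <- step[k] + (min_sep - sep)
    }
  }
  total <- h_k[1] / 2 * cos(theta_k[1]) + sum(step) + h_k[n] / 2 * cos(theta_k[n])
  margin <- 40
  if (total + 2 * margin > size) abort("spec too large: bodies exceed image bounds.")
  y_c <- (size - total) / 2 + h_k[1] / 2 * cos(theta_k[1]) + c(0, cumsum(step))

  # analytic landmarks (rotation of (0, h/2) and (w/2, 0) by theta)
  lower_ref <- cbind(x = x_c - sin(theta_k) * h_k / 2, y = y_c + cos(theta_k) * h_k / 2)
  upper_ref <- cbind(x = x_c + sin(theta_k) * h_k / 2, y = y_c - cos(theta_k) * h_k / 2)
  right_ref <- cbind(x = x_c + cos(theta_k) * w_k / 2, y = y_c + sin(theta_k) * w_k / 2)
  ex <- (w_k * abs(cos(theta_k)) + h_k * abs(sin(theta_k))) / 2
  ey <- (w_k * abs(sin(theta_k)) + h_k * abs(cos(theta_k))) / 2
  boxes <- tibble(
    label = labels,
    x_min = x_c - ex, y_min = y_c - ey, x_max = x_c + ex, y_max = y_c + ey
  )

  a <- spec$foramen_semiaxes[1]; b <- spec$foramen_semiaxes[2]
  f_xc <- boxes$x_max + f_off + a
  f_yc <- y_c
  f_left <- cbind(x = f_xc - a, y = f_yc)
  fboxes <- tibble(
    label = rep("FORAMEN", n),
    x_min = f_xc - a, y_min = f_yc - b, x_max = f_xc + a, y_max = f_yc + b
  )

  iv <- tibble(
    upper = labels[-n], lower = labels[-1],
    p1_x = lower_ref[-n, "x"], p1_y = lower_ref[-n, "y"],
    p2_x = upper_ref[-1, "x"], p2_y = upper_ref[-1, "y"]
  )
  iv$distance_px <- sqrt((iv$p2_x - iv$p1_x)^2 + (iv$p2_y - iv$p1_y)^2)
  vf <- tibble(
    vertebra = labels,
    p1_x = right_ref[, "x"], p1_y = right_ref[, "y"],
    p2_x = f_left[, "x"], p2_y = f_left[, "y"]
  )
  vf$distance_px <- sqrt((vf$p2_x - vf$p1_x)^2 + (vf$p2_y - vf$p1_y)^2)

  # render: background (air), thickness-modulated soft tissue, foramina,
  # bodies (in that order). The soft tissue is a flat-capped vertical
  # capsule following the (curved) spine axis, at full intensity on a
  # plateau around the axis and fading toward the skin line, as neck
  # attenuation does on a lateral view.
  bg_i <- spec$intensity[["background"]]
  soft_i <- spec$intensity[["soft_tissue"]]
  img <- matrix(bg_i, size, size)
  halo_r <- 175
  plateau_r <- 130
  edge_i <- bg_i  # thickness tapers to zero at the skin line
  axis_x <- stats::approx(y_c, x_c, xout = seq_len(size) - 1, rule = 2)$y
  X <- matrix(rep(seq_len(size) - 1, each = size), size)
  adx <- abs(X - axis_x)
  # the neck column fills the frame vertically, as on a clinical lateral view
  soft <- adx <= halo_r
  soft_val <- soft_i - (soft_i - edge_i) *
    clamp((adx - plateau_r) / (halo_r - plateau_r), 0, 1)
  img[soft] <- soft_val[soft]
  soft_mask <- matrix(0L, size, size)
  soft_mask[soft] <- 255L
  for (k in seq_len(n)) {
    img <- fill_ellipse(img, f_xc[k], f_yc[k], a, b, spec$intensity[["foramen"]])
  }
  body_mask <- matrix(0L, size, size)
  for (k in seq_len(n)) {
    img <- fill_round_rect(
      img, x_c[k], y_c[k], w_k[k], h_k[k], theta_k[k],
      spec$corner_radius, spec$intensity[["bone"]]
    )
    body_mask <- fill_round_rect(
      body_mask, x_c[k], y_c[k], w_k[k], h_k[k], theta_k[k],
      spec$corner_radius, 255L
    )
  }
  storage.mode(body_mask) <- "integer"

  # illumination plane (modulates the tissue signal: full amplitude at bone
  # level, none in air, as beam-intensity variation does) + noise
  gx <- matrix(rep(seq_len(size) - 1, each = size), size) / (size - 1) - 0.5
  gy <- matrix(rep(seq_len(size) - 1, times = size), size) / (size - 1) - 0.5
  bone_i <- spec$intensity[["bone"]]
  img <- img + spec$illumination_gradient_amplitude * (gx + gy) *
    (img - bg_i) / (bone_i - bg_i)
  if (spec$gaussian_noise_sigma > 0) {
    img <- img + stats::rnorm(size * size, 0, spec$gaussian_noise_sigma)
  }
  if (spec$salt_pepper_fraction > 0) {
    n_sp <- round(spec$salt_pepper_fraction * size * size)
    if (n_sp > 0) {
      idx <- sample.int(size * size, n_sp)
      img[idx] <- ifelse(stats::runif(n_sp) < 0.5, 0, 255)
    }
  }
  img <- gray_image(clamp(round(img), 0, 255))

  truth <- structure(
    list(
      labels = labels,
      boxes = dplyr::bind_rows(boxes, fboxes),
      reference_points = tibble(
        label = labels,
        upper_x = upper_ref[, "x"], upper_y = upper_ref[, "y"],
        lower_x = lower_ref[, "x"], lower_y = lower_ref[, "y"]
      ),
      foramen_centers = tibble(vertebra = labels, x = f_xc, y = f_yc),
      intervertebral_distances = iv,
      vertebra_foramen_distances = vf,
      body_mask = body_mask,
      soft_mask = soft_mask,
      spec = spec
    ),
    class = "phantom_truth"
  )
  list(image = img, truth = truth)
}

#' Export a phantom to disk
#'
#' Writes the phantom image as PNG, its boxes as a YOLO label file (class
#' map from [cspine_class_map()]), and the full ground truth as JSON.
#' Normalized labels round-trip through [read_yolo_labels()] to within 1 px
#' of the true boxes.
#'
#' @param image Phantom gray image.
#' @param truth `phantom_truth` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default `"phantom"`).
#' @param class_map Named integer vector, see [cspine_class_map()].
#' @return Invisibly, the three paths written.
#' @export
export_phantom <- function(image, truth, dir, stem = "phantom",
                           class_map = cspine_class_map()) {
  stopifnot(inherits(truth, "phantom_truth"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort(sprintf("cannot create output directory %s", dir))
  size_x <- ncol(image); size_y <- nrow(image)
  png_path <- file.path(dir, paste0(stem, ".png"))
  write_image(image, png_path)
  b <- truth$boxes
  lbl <- tibble(
    class_id = unname(class_map[b$label]),
    x_center = (b$x_min + b$x_max) / 2 / size_x,
    y_center = (b$y_min + b$y_max) / 2 / size_y,
    box_width = (b$x_max - b$x_min) / size_x,
    box_height = (b$y_max - b$y_min) / size_y
  )
  if (anyNA(lbl$class_id)) abort("phantom labels missing from `class_map`.")
  label_path <- file.path(dir, paste0(stem, ".txt"))
  write_yolo_labels(lbl, label_path)
  truth_path <- file.path(dir, paste0(stem, "_truth.json"))
  jsonlite::write_json(
    list(
      boxes = truth$boxes, reference_points = truth$reference_points,
      foramen_centers = truth$foramen_centers,
      intervertebral_distances = truth$intervertebral_distances,
      vertebra_foramen_distances = truth$vertebra_foramen_distances
    ),
    truth_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(c(image = png_path, labels = label_path, truth = truth_path))
}
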