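test_that("ROI enhancement recovers a clean two-level blob", {
  # blob chosen open w.r.t. the 3x3 cross (rounded corners), since opening
  # necessarily rounds sharp corners
  dil <- function(m) {
    s <- function(dy, dx) {
      ri <- pmin(pmax(seq_len(nrow(m)) + dy, 1), nrow(m))
      ci <- pmin(pmax(seq_len(ncol(m)) + dx, 1), ncol(m))
      m[ri, ci]
    }
    m | s(1, 0) | s(-1, 0) | s(0, 1) | s(0, -1)
  }
  core <- matrix(FALSE, 40, 40); core[13:28, 15:30] <- TRUE
  blob <- dil(core)
  roi <- matrix(40L, 40, 40); roi[blob] <- 200L
  out <- enhance_roi(gray_image(roi))
  expect_identical(out == 255L, blob)

  expect_error(enhance_roi(gray_image(matrix(99L, 20, 20))), "degenerate")
  expect_error(enhance_roi(gray_image(matrix(0:24, 5, 5))), "8x8")

  # 1-px salt specks are absent after opening (no tiny component survives)
  roi2 <- roi
  set.seed(6)
  specks <- cbind(sample(c(2:10, 32:39), 6), sample(2:39, 6))
  roi2[specks] <- 230L
  out2 <- enhance_roi(gray_image(roi2))
  comps <- oracle_components(out2)
  expect_true(all(vapply(comps, length, integer(1)) >= 5))
})

test_that("largest component matches the flood-fill oracle", {
  two <- matrix(0L, 20, 20)
  two[2:6, 2:11] <- 255L   # area 50
  two[15:17, 15:17] <- 0L; two[15, 15:17] <- 255L; two[16, 15:17] <- 255L; two[16, 17] <- 255L
  lc <- largest_component(two)
  expect_equal(lc$area, 50)
  expect_true(all(lc$mask[2:6, 2:11] == 255L))
  expect_equal(sum(lc$mask == 255L), 50)

  single <- matrix(0L, 10, 10); single[3:5, 3:5] <- 255L
  expect_identical(largest_component(single)$mask, single)

  expect_error(largest_component(matrix(0L, 5, 5)), "no component")

  set.seed(71)
  for (i in 1:100) {
    b <- rand_binary(sample(5:20, 1), sample(5:20, 1), p = runif(1, 0.2, 0.7))
    if (all(b == 0L)) next
    expect_identical(largest_component(b)$mask, oracle_largest_component_mask(b))
  }
})

test_that("directional extrema match the exhaustive scan", {
  rect <- matrix(0L, 64, 64); rect[31:40, 11:20] <- 255L
  ex <- directional_extrema(rect)
  expect_equal(unname(ex$bottom_left), c(10, 39))
  expect_equal(unname(ex$bottom_right), c(19, 39))
  expect_equal(unname(ex$top_left), c(10, 30))
  expect_equal(unname(ex$top_right), c(19, 30))

  px <- matrix(0L, 10, 10); px[6, 6] <- 255L
  ex1 <- directional_extrema(px)
  for (p in ex1) expect_equal(unname(p), c(5, 5))

  set.seed(81)
  for (i in 1:100) {
    b <- rand_binary(sample(4:16, 1), sample(4:16, 1), p = 0.4)
    if (all(b == 0L)) next
    got <- directional_extrema(b)
    want <- oracle_extrema(b)
    for (nm in names(want)) expect_equal(got[[nm]], want[[nm]])
  }
})

test_that("reference points are exact edge midpoints on rectangles", {
  # [10,20) x [30,40): midpoint column round(14.5) -> 14 (half-to-even)
  mask <- rect_mask(10, 20, 30, 40)
  rp <- reference_points(mask)
  expect_equal(unname(rp$lower_ref), c(14, 39))
  expect_equal(unname(rp$upper_ref), c(14, 30))
  expect_false(rp$fallback)

  one <- matrix(0L, 12, 12); one[6, 6] <- 255L
  rp1 <- reference_points(largest_component(one))
  expect_equal(unname(rp1$lower_ref), c(5, 5))
  expect_equal(unname(rp1$upper_ref), c(5, 5))

  # closed form on random rectangles
  set.seed(91)
  for (i in 1:25) {
    x0 <- sample(0:20, 1); x1 <- x0 + sample(3:20, 1)
    y0 <- sample(0:20, 1); y1 <- y0 + sample(3:20, 1)
    rp2 <- reference_points(rect_mask(x0, x1, y0, y1))
    expect_equal(unname(rp2$lower_ref), c(round((x0 + x1 - 1) / 2), y1 - 1))
    expect_equal(unname(rp2$upper_ref), c(round((x0 + x1 - 1) / 2), y0))
  }
})

test_that("reference points are translation-equivariant", {
  set.seed(101)
  base <- rand_binary(20, 20, p = 0.35)
  base[8:12, 8:12] <- 255L
  m0 <- largest_component(base)
  rp0 <- reference_points(m0)
  for (shift in list(c(3, 0), c(0, 7), c(13, 5))) {
    m1 <- largest_component(base, offset = shift)
    rp1 <- reference_points(m1)
    expect_equal(unname(rp1$lower_ref), unname(rp0$lower_ref) + shift)
    expect_equal(unname(rp1$upper_ref), unname(rp0$upper_ref) + shift)
    expect_equal(
      euclidean_distance(rp1$lower_ref, rp1$upper_ref),
      euclidean_distance(rp0$lower_ref, rp0$upper_ref)
    )
  }
})

test_that("euclidean distance is exact and metric", {
  expect_identical(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_identical(euclidean_distance(c(7, 2), c(7, 2)), 0)
  set.seed(111)
  for (i in 1:100) {
    p <- runif(2, -50, 50); q <- runif(2, -50, 50); r <- runif(2, -50, 50)
    d <- euclidean_distance(p, q)
    expect_equal(d, sqrt(sum((q - p)^2)), tolerance = 1e-9)
    expect_equal(d, euclidean_distance(q, p))
    expect_gte(d, 0)
    expect_lte(d, euclidean_distance(p, r) + euclidean_distance(r, q) + 1e-12)
  }
})

test_that("intervertebral measurement uses facing reference points", {
  # aligned rectangles with a 14-px vertical gap
  up <- rect_mask(10, 30, 10, 20)
  lo <- rect_mask(10, 30, 33, 43)  # gap rows 20..32 -> 39 - 19 - ... distance 14
  m <- measure_intervertebral(up, lo, c("C2", "C3"))
  expect_equal(m$distance_px, 14)
  expect_equal(m$kind, "intervertebral")

  # 3-px horizontal offset, 4-px point gap -> 3-4-5
  up2 <- rect_mask(10, 20, 10, 20)   # lower_ref (14, 19)
  lo2 <- rect_mask(13, 22, 23, 33)   # upper_ref (17, 23)
  m2 <- measure_intervertebral(up2, lo2, c("C3", "C4"))
  expect_equal(m2$distance_px, 5)
})

test_that("vertebra-foramen measurement spans the facing boundaries", {
  v <- rect_mask(5, 25, 20, 40, w = 80)   # right-boundary midpoint (24, 30)
  f <- rect_mask(54, 65, 24, 36, w = 80)  # left-boundary midpoint (54, 30)
  m <- measure_vertebra_foramen(v, f, c("C4", "FORAMEN"))
  expect_equal(m$kind, "vertebra_foramen")
  expect_equal(m$p1_x, 24)
  expect_equal(m$p2_x, 54)
  expect_equal(m$distance_px, 30)

  # 6-px horizontal and 8-px vertical midpoint separation -> 10
  v2 <- rect_mask(10, 20, 10, 20)    # right mid (19, 14) [round(14.5) -> 14]
  f2 <- rect_mask(25, 35, 18, 28)    # left mid (25, 22)
  m2 <- measure_vertebra_foramen(v2, f2, c("C5", "FORAMEN"))
  expect_equal(abs(m2$p2_x - m2$p1_x), 6)
  expect_equal(abs(m2$p2_y - m2$p1_y), 8)
  expect_equal(m2$distance_px, 10)

  # mirrored geometry: foramen on the left uses the vertebra's left boundary
  m3 <- measure_vertebra_foramen(f2, v2, c("C5", "FORAMEN"))
  expect_equal(m3$p1_x, 25)
  expect_equal(m3$p2_x, 19)
})

test_that("full pipeline measures phantoms and degrades gracefully", {
  ph <- generate_phantom(phantom_spec(seed = 61))
  rep <- run_pipeline(ph$image, oracle_detector(ph$truth), image_id = "p61")
  iv <- rep$measurements[rep$measurements$kind == "intervertebral", ]
  expect_equal(nrow(iv), 5)
  errs <- intervertebral_errors(ph, rep)
  expect_lte(max(errs), 3)
  expect_equal(length(rep$missing_levels), 0)

  # detector returning nothing: empty report, all levels missing
  null_detector <- function(image, region = NULL) detections()
  rep0 <- run_pipeline(ph$image, null_detector, image_id = "none")
  expect_equal(nrow(rep0$measurements), 0)
  expect_setequal(rep0$missing_levels, c("C2", "C3", "C4", "C5", "C6", "C7"))

  # determinism: identical runs give identical reports
  rep2 <- run_pipeline(ph$image, oracle_detector(ph$truth), image_id = "p61")
  expect_identical(rep, rep2)

  # tidy/glance accessors
  td <- tidy(rep)
  expect_true(all(c("image_id", "level_pair", "distance_px") %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$n_intervertebral, 5)
})
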