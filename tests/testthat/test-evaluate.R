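test_that("detection matching matches the brute-force oracle", {
  t1 <- tibble::tibble(label = "C3", x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  p_good <- detections("C3", 1, 0, 11, 10, 0.9)  # IoU 9/11 ~ 0.82
  c1 <- match_detections(p_good, t1, 0.5)
  expect_equal(c1$tp, 1); expect_equal(c1$fp, 0); expect_equal(c1$fn, 0)

  p_bad <- detections("C4", 0, 0, 10, 10, 0.9)
  c2 <- match_detections(p_bad, t1, 0.5)
  expect_equal(sum(c2$tp), 0)
  expect_equal(sum(c2$fp), 1)
  expect_equal(sum(c2$fn), 1)
  expect_true(all(c2$tn == 0))

  expect_error(match_detections(p_bad, t1, 0), "iou_threshold")

  set.seed(123)
  for (i in 1:30) {
    labs <- c("C2", "C3", "FORAMEN")
    mk <- function(n) {
      x0 <- runif(n, 0, 80); y0 <- runif(n, 0, 80)
      tibble::tibble(
        label = sample(labs, n, replace = TRUE), x_min = x0, y_min = y0,
        x_max = x0 + runif(n, 5, 20), y_max = y0 + runif(n, 5, 20)
      )
    }
    truth <- mk(sample(1:8, 1))
    pred <- dplyr::mutate(mk(sample(1:10, 1)), confidence = runif(dplyr::n()))
    got <- match_detections(pred, truth, 0.3)
    want <- oracle_match(pred, truth, 0.3)
    expect_equal(
      as.data.frame(got[order(got$label), c("label", "tp", "fp", "fn")]),
      want[order(want$label), c("label", "tp", "fp", "fn")],
      ignore_attr = TRUE
    )
  }
})

test_that("rates follow the confusion-count definitions, NA when undefined", {
  r <- rates(list(tp = 9, fp = 1, fn = 1, tn = 0))
  expect_equal(r$accuracy, 9 / 11)
  expect_equal(r$precision, 0.9)
  expect_equal(r$recall, 0.9)

  r0 <- rates(list(tp = 0, fp = 0, fn = 0, tn = 0))
  expect_true(all(is.na(c(r0$accuracy, r0$precision, r0$recall))))

  r1 <- rates(list(tp = 5, fp = 0, fn = 0, tn = 0))
  expect_equal(unlist(r1), c(accuracy = 1, precision = 1, recall = 1))

  expect_error(rates(list(tp = -1, fp = 0, fn = 0, tn = 0)), "non-negative")
})

test_that("average precision equals the staircase-integration oracle", {
  allgood <- tibble::tibble(confidence = c(0.9, 0.8, 0.7), is_tp = TRUE)
  expect_equal(average_precision(allgood, 3)$ap, 1)

  allbad <- tibble::tibble(confidence = c(0.9, 0.8), is_tp = FALSE)
  expect_equal(average_precision(allbad, 2)$ap, 0)

  expect_error(average_precision(allgood, 0), "n_truth")

  mixed <- tibble::tibble(
    confidence = c(0.95, 0.9, 0.8, 0.7, 0.6, 0.5),
    is_tp = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  )
  expect_equal(
    average_precision(mixed, 3)$ap,
    oracle_ap(mixed$confidence, mixed$is_tp, 3),
    tolerance = 1e-12
  )

  set.seed(131)
  for (i in 1:50) {
    n <- sample(2:20, 1)
    sc <- tibble::tibble(confidence = runif(n), is_tp = runif(n) < 0.5)
    nt <- max(1, sum(sc$is_tp)) + sample(0:3, 1)
    pr <- average_precision(sc, nt)
    expect_equal(pr$ap, oracle_ap(sc$confidence, sc$is_tp, nt), tolerance = 1e-12)
    expect_true(all(diff(pr$curve$recall) >= 0))
    expect_gte(pr$ap, 0); expect_lte(pr$ap, 1)
    # invariance under monotone confidence rescaling
    sc2 <- dplyr::mutate(sc, confidence = plogis(3 * confidence - 1))
    expect_equal(average_precision(sc2, nt)$ap, pr$ap, tolerance = 1e-12)
  }
})

test_that("mAP averages defined class APs and skips undefined ones", {
  expect_equal(mean_ap(c(1, 0.5)), 0.75)
  expect_equal(mean_ap(0.9), 0.9)
  expect_equal(mean_ap(c(0.8, NA)), 0.8)
  expect_error(mean_ap(c(NA_real_, NA_real_)), "no class")
})

test_that("ppmcc matches the direct covariance oracle and its invariances", {
  expect_equal(ppmcc(1:5, 2 * (1:5) + 1), 1)
  expect_equal(ppmcc(1:5, -(1:5)), -1)
  expect_error(ppmcc(1:3, 1:4), "equal lengths")
  expect_error(ppmcc(1, 2), "two pairs")
  expect_error(ppmcc(rep(1, 5), 1:5), "constant")

  set.seed(141)
  for (i in 1:50) {
    x <- rnorm(sample(3:30, 1)); y <- rnorm(length(x))
    expect_equal(ppmcc(x, y), oracle_pearson(x, y), tolerance = 1e-12)
    # positive affine invariance
    expect_equal(ppmcc(2.5 * x + 3, y), ppmcc(x, y), tolerance = 1e-12)
  }
})

test_that("matching at vanishing IoU with correct labels leaves only count gaps", {
  set.seed(151)
  truth <- tibble::tibble(
    label = "C2", x_min = c(0, 30, 60), y_min = 0, x_max = c(10, 40, 70), y_max = 10
  )
  pred <- detections("C2", c(1, 31), 1, c(9, 39), 9, c(0.9, 0.8))
  cnt <- match_detections(pred, truth, 1e-9)
  expect_equal(cnt$fn, max(0, nrow(truth) - nrow(pred)))
})

test_that("agreement reporting reproduces per-case correlation tables", {
  set.seed(161)
  reps <- lapply(1:3, function(i) {
    m <- tibble::tibble(
      kind = rep(c("intervertebral", "vertebra_foramen"), each = 5),
      from_label = rep(c("C2", "C3", "C4", "C5", "C6"), 2),
      to_label = c(c("C3", "C4", "C5", "C6", "C7"), rep("FORAMEN", 5)),
      p1_x = 0, p1_y = 0, p2_x = 0, p2_y = 0,
      distance_px = runif(10, 5, 30)
    )
    measurement_report(paste0("case", i), m)
  })
  self <- agreement_report(reps, reps)
  expect_true(all(self$ppmcc[self$case != "average"] == 1))
  expect_equal(self$ppmcc[self$case == "average"], c(1, 1))

  # shuffling one case across levels lowers its correlation
  shuffled <- reps
  m <- shuffled[[2]]$measurements
  iv <- which(m$kind == "intervertebral")
  m$distance_px[iv] <- m$distance_px[rev(iv)]
  shuffled[[2]] <- measurement_report("case2", m)
  ag <- agreement_report(shuffled, reps)
  r2 <- ag$ppmcc[ag$case == "case2" & ag$kind == "intervertebral"]
  expect_lt(r2, 1)

  expect_error(
    agreement_report(reps[[1]], measurement_report("other")),
    "no common"
  )
})

test_that("detector evaluation wraps matching, rates and mAP", {
  ph <- generate_phantom(phantom_spec(seed = 8))
  det <- oracle_detector(ph$truth)(ph$image, NULL)
  det$confidence <- seq(0.95, by = -0.01, length.out = nrow(det))
  ev <- evaluate_detections(det, ph$truth$boxes)
  expect_equal(ev$map, 1)
  expect_true(all(ev$rates$precision == 1, na.rm = TRUE))
  expect_true(all(ev$rates$recall == 1, na.rm = TRUE))
  expect_s3_class(ev$curves[["C2"]], "pr_curve")
})
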