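test_that("resize preserves identity, constants and local means", {
  set.seed(1)
  img <- rand_gray(512, 512)
  expect_identical(resize_to_standard(img, 512), img)

  const <- gray_image(matrix(100L, 64, 200))
  out <- resize_to_standard(const, 512)
  expect_equal(dim(out), c(512L, 512L))
  expect_true(all(out == 100L))

  checker <- gray_image(outer(1:1024, 1:1024, function(i, j) ((i + j) %% 2) * 255L))
  down <- resize_to_standard(checker, 512)
  # oracle: direct 2x2 block averaging
  block_mean <- mean(c(0, 255, 255, 0))
  expect_lt(abs(mean(down) - block_mean), 1)
  expect_lt(abs(mean(down) - mean(checker)), 1)

  expect_error(resize_to_standard(img, 0), "target")
})

test_that("median filter matches the per-pixel sorting oracle", {
  const <- gray_image(matrix(50L, 10, 10))
  expect_identical(median_filter(const, 3), const)

  salt <- matrix(0L, 9, 9); salt[5, 5] <- 255L
  expect_true(all(median_filter(gray_image(salt), 3) == 0L))

  expect_error(median_filter(const, 4), "odd")

  set.seed(21)
  for (i in 1:100) {
    h <- sample(3:12, 1); w <- sample(3:12, 1)
    img <- rand_gray(h, w)
    win <- sample(c(3, 5), 1)
    expect_identical(median_filter(img, win), oracle_median_filter(img, win))
  }
})

test_that("median filter is idempotent on constant and step images", {
  step <- gray_image(cbind(matrix(0L, 12, 6), matrix(255L, 12, 6)))
  once <- median_filter(step, 3)
  expect_identical(median_filter(once, 3), once)
  const <- gray_image(matrix(7L, 8, 8))
  expect_identical(median_filter(median_filter(const, 3), 3), median_filter(const, 3))
})

test_that("histogram equalization is monotone and flattens the CDF", {
  const <- gray_image(matrix(42L, 10, 10))
  expect_identical(equalize_hist(const), const)

  two <- gray_image(rbind(matrix(0L, 5, 10), matrix(255L, 5, 10)))
  out <- equalize_hist(two)
  expect_equal(sort(unique(as.vector(out))), c(0L, 255L))

  # oracle: sup distance between the empirical CDF and the uniform CDF
  sup_dev <- function(img) {
    cdf <- cumsum(tabulate(as.vector(img) + 1L, 256L)) / length(img)
    max(abs(cdf - (1:256) / 256))
  }
  set.seed(33)
  for (i in 1:5) {
    img <- gray_image(matrix(
      as.integer(pmin(pmax(round(rnorm(64 * 64, 100, 18)), 0), 255)), 64, 64
    ))
    expect_lt(sup_dev(equalize_hist(img)), sup_dev(img))
  }

  # monotone: rank order preserved up to ties on a random image
  img <- rand_gray(32, 32, seed = 8)
  out <- equalize_hist(img)
  ord <- order(as.vector(img))
  expect_true(all(diff(as.vector(out)[ord]) >= 0))
})

test_that("CLAHE degenerates to global HE and raises local contrast", {
  const <- gray_image(matrix(77L, 40, 40))
  expect_identical(clahe(const, 2, 8), const)

  img <- rand_gray(64, 64, seed = 13)
  expect_identical(clahe(img, clip = 1e9, tiles = 1), equalize_hist(img))

  # gradient with local texture: tile-wise sd should not decrease in >=90%
  # of tiles (oracle computes the per-tile sd before and after)
  set.seed(14)
  base <- outer(seq_len(64), seq_len(64), function(i, j) 60 + j)
  tex <- matrix(sample(-6:6, 64 * 64, replace = TRUE), 64, 64)
  img2 <- gray_image(pmin(pmax(round(base + tex), 0), 255))
  out2 <- clahe(img2, 2, 8)
  sds <- function(m) {
    vapply(0:63, function(k) {
      ti <- k %% 8; tj <- k %/% 8
      stats::sd(m[(ti * 8 + 1):(ti * 8 + 8), (tj * 8 + 1):(tj * 8 + 8)])
    }, numeric(1))
  }
  expect_gte(mean(sds(out2) >= sds(img2)), 0.9)
})

test_that("Otsu threshold equals the exhaustive-search oracle", {
  bimodal <- gray_image(rbind(matrix(10L, 8, 16), matrix(200L, 8, 16)))
  expect_identical(otsu_threshold(bimodal), 10L)

  expect_error(otsu_threshold(gray_image(matrix(9L, 4, 4))), "degenerate")

  set.seed(41)
  for (i in 1:200) {
    img <- gray_image(matrix(
      as.integer(sample(0:255, 256, replace = TRUE, prob = runif(256)^2)), 16, 16
    ))
    if (length(unique(as.vector(img))) < 2) next
    expect_identical(otsu_threshold(img), as.integer(oracle_otsu(img)))
  }
})

test_that("adaptive thresholding matches the direct local-mean oracle", {
  const <- gray_image(matrix(120L, 20, 20))
  expect_true(all(adaptive_threshold(const, 31, 5) == 255L))
  # unreachable threshold (local mean + 256 exceeds any intensity)
  expect_true(all(adaptive_threshold(const, 31, -256) == 0L))
  expect_error(adaptive_threshold(const, 4, 5), "odd")

  sq <- matrix(20L, 60, 60)
  sq[21:40, 21:40] <- 220L
  out <- adaptive_threshold(gray_image(sq), 31, 5)
  expect_true(all(out[26:35, 26:35] == 255L))  # square interior
  expect_true(all(out[18:20, 21:40] == 0L))    # dark shadow ring beside the square

  set.seed(55)
  for (i in 1:30) {
    img <- rand_gray(sample(5:14, 1), sample(5:14, 1))
    blk <- sample(c(3, 5), 1)
    off <- runif(1, -10, 10)
    expect_identical(adaptive_threshold(img, blk, off), oracle_adaptive(img, blk, off))
  }
})

test_that("windowed operations map [0,255] into [0,255]", {
  set.seed(66)
  for (i in 1:10) {
    img <- rand_gray(20, 20)
    for (out in list(
      median_filter(img, 3), equalize_hist(img), clahe(img, 2, 4),
      resize_to_standard(img, 37), gaussian_blur(img, 1.5)
    )) {
      expect_true(min(out) >= 0L && max(out) <= 255L)
      expect_true(is.integer(out))
    }
  }
})

test_that("binarize pipeline is deterministic and produces a clean spine mask", {
  expect_error(binarize_pipeline(gray_image(matrix(5L, 64, 64))), "degenerate")

  ph <- generate_phantom(phantom_spec(
    seed = 4, gaussian_noise_sigma = 0, salt_pepper_fraction = 0
  ))
  bin <- binarize_pipeline(ph$image)
  expect_true(all(bin %in% c(0L, 255L)))
  # every interior vertebral-body pixel is white; the median filter may
  # round isolated single corner pixels of the rasterized boundary
  bm <- ph$truth$body_mask
  interior <- cervometry:::erode_cross(bm)
  expect_true(all(bin[interior == 255L] == 255L))
  expect_gte(mean(bin[bm == 255L] == 255L), 0.999)
  # at least 99% of far-background (air) pixels are black
  air <- ph$truth$soft_mask == 0L & ph$truth$body_mask == 0L
  expect_gte(mean(bin[air] == 0L), 0.99)

  ph2 <- generate_phantom(phantom_spec(seed = 9))
  expect_identical(binarize_pipeline(ph2$image), binarize_pipeline(ph2$image))
})

test_that("preprocess configuration validates its fields", {
  expect_error(preprocess_config(median_window = 4), "odd")
  expect_error(preprocess_config(adaptive_block = 2), "odd")
  expect_error(preprocess_config(target_size = 16), "target_size")
  expect_error(preprocess_config(clahe_clip = 0), "positive")
  cfg <- preprocess_config(use_clahe = FALSE)
  expect_false(cfg$use_clahe)
})
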