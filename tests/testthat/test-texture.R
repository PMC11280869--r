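test_that("grayscale rendering maps the fixed physical range linearly", {
  z <- matrix(0, 4, 4)
  expect_equal(to_grayscale(z, "delta")$pixels, z)
  half <- matrix(pi / 2, 4, 4)
  expect_equal(to_grayscale(half, "delta")$pixels, matrix(0.5, 4, 4))
  # masked pixels stay NA and clipping is counted
  m <- matrix(c(-0.1, pi + 0.1, 1, 1), 2, 2)
  g <- to_grayscale(m, "delta", mask = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  expect_equal(g$n_clipped, 2)
  expect_true(is.na(g$pixels[2, 2]))
  expect_error(to_grayscale(matrix(NA_real_, 2, 2), "delta"), "foreground")
})

test_that("histogram summary: peak normalization and high-gray fraction", {
  u <- as_gray(matrix(0.55, 8, 8))
  hs <- histogram_summary(u, bins = 10)
  expect_equal(sum(hs$normalized == 1), 1)
  expect_equal(sum(hs$counts), 64)
  x <- matrix(c(rep(0.9, 32), rep(0.1, 32)), 8, 8)
  hs2 <- histogram_summary(as_gray(x), bins = 10, high_threshold = 0.8)
  expect_equal(hs2$high_gray_fraction, 0.5)
  # linear ramp: flat histogram within discretization
  ramp <- matrix(seq(0, 1 - 1e-9, length.out = 400), 20, 20)
  hs3 <- histogram_summary(as_gray(ramp), bins = 8)
  expect_true(all(abs(hs3$counts - 50) <= 1))
})

test_that("kurtosis and skewness follow the raw population-moment forms", {
  two_point <- c(0.2, 0.8, 0.2, 0.8)
  st <- distribution_stats(two_point)
  expect_equal(st$skewness, 0, tolerance = 1e-12)
  # hand evaluation: z = +-1 for all four points, so mean(z^4) = 1
  expect_equal(st$kurtosis, 1, tolerance = 1e-12)
  set.seed(2024)
  z <- rnorm(1e6)
  st2 <- distribution_stats(z)
  expect_equal(st2$kurtosis, 3, tolerance = 0.05 / 3)
  expect_equal(st2$skewness, 0, tolerance = 0.01)
  expect_warning(st3 <- distribution_stats(rep(0.4, 10)), "constant")
  expect_true(is.na(st3$kurtosis))
})

test_that("glcm: constant image, hand-counted checkerboard, normalization", {
  const <- glcm(as_gray(matrix(0.4, 6, 6)), Ng = 8)
  expect_equal(sum(const), 1, tolerance = 1e-12)
  expect_equal(sum(const > 0), 1)
  expect_equal(const[4, 4], 1)   # level floor(0.4 * 8) + 1

  cb <- as_gray((matrix(rep(1:6, 6), 6, 6) +
                 matrix(rep(1:6, each = 6), 6, 6)) %% 2 * 0.99)
  p <- glcm(cb, Ng = 2, distance = 1, angles = 0, symmetric = TRUE)
  expect_equal(p[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(p[2, 1], 0.5, tolerance = 1e-12)
  expect_equal(p[1, 1] + p[2, 2], 0)

  set.seed(33)
  for (i in 1:100) {
    img <- as_gray(matrix(runif(64), 8, 8))
    p <- glcm(img, Ng = sample(2:16, 1),
              distance = sample(1:2, 1), symmetric = sample(c(TRUE, FALSE), 1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("background pixels never contribute co-occurrence pairs", {
  x <- matrix(0.2, 6, 6)
  x[, 4:6] <- 0.9
  mask <- matrix(TRUE, 6, 6); mask[, 4:6] <- FALSE
  p <- glcm(as_gray(x, mask = mask), Ng = 4, angles = 0)
  # only level floor(0.2*4)+1 = 1 pairs remain
  expect_equal(p[1, 1], 1)
})

test_that("glcm features match hand values and the naive double-loop oracle", {
  cb <- as_gray((matrix(rep(1:6, 6), 6, 6) +
                 matrix(rep(1:6, each = 6), 6, 6)) %% 2 * 0.99)
  p <- glcm(cb, Ng = 2, distance = 1, angles = 0, symmetric = TRUE)
  f <- glcm_features(p)
  expect_equal(f$contrast, 1)
  expect_equal(f$energy, 0.5)
  expect_equal(f$homogeneity, 0.5)
  expect_equal(f$correlation, -1)

  const <- glcm(as_gray(matrix(0.4, 6, 6)), Ng = 8)
  fc <- glcm_features(const)
  expect_equal(fc$contrast, 0)
  expect_equal(fc$energy, 1)
  expect_equal(fc$homogeneity, 1)
  expect_true(is.na(fc$correlation))

  set.seed(44)
  for (i in 1:50) {
    img <- as_gray(matrix(runif(256), 16, 16))
    p <- glcm(img, Ng = 16)
    a <- glcm_features(p)
    b <- naive_glcm_features(unclass(p))
    for (nm in names(b)) expect_lt(abs(a[[nm]] - b[[nm]]), 1e-12)
  }
})

test_that("features are bit-identical across repeated runs on the same image", {
  set.seed(50)
  img <- as_gray(matrix(runif(64^2), 64, 64))
  cfg <- pipeline_config()
  a <- list(glcm_features(glcm(img)), distribution_stats(img),
            tamura_contrast(img), tamura_coarseness(img),
            tamura_line_likeness(img))
  b <- list(glcm_features(glcm(img)), distribution_stats(img),
            tamura_contrast(img), tamura_coarseness(img),
            tamura_line_likeness(img))
  expect_identical(a, b)
})
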