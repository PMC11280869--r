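test_that("identity decomposes into identity factors", {
  f <- lc_decompose(diag(4))
  expect_true(f$ok)
  expect_equal(f$M_D, diag(4), tolerance = 1e-12)
  expect_equal(f$M_Delta, diag(4), tolerance = 1e-12)
  expect_equal(f$M_R, diag(4), tolerance = 1e-12)
  expect_equal(c(f$D, f$Delta, f$R, f$delta), c(0, 0, 0, 0),
               tolerance = 1e-8)
})

test_that("a pure linear retarder is returned unchanged as the retarder factor", {
  m <- linear_retarder(0.7, 1.1)
  f <- lc_decompose(unclass(m))
  expect_equal(f$M_R, unclass(m), tolerance = 1e-10)
  expect_equal(f$M_D, diag(4), tolerance = 1e-10)
  expect_equal(f$M_Delta, diag(4), tolerance = 1e-10)
  expect_equal(f$delta, 1.1, tolerance = 1e-10)
  expect_equal(f$theta, 0.7, tolerance = 1e-10)
})

test_that("factor product reproduces the input on random physical matrices", {
  set.seed(123)
  worst <- 0
  for (i in 1:500) {
    M <- random_physical_mm(with_circular = (i %% 2 == 0))$M
    M <- M / M[1, 1]
    f <- lc_decompose(M)
    expect_true(f$ok)
    worst <- max(worst, max(abs(f$M_Delta %*% f$M_R %*% f$M_D - M)))
  }
  expect_lt(worst, 1e-8)
})

test_that("construction parameters (Delta, delta, theta, D) are recovered", {
  M <- pure_depolarizer(0.9, 0.9, 0.8) %*% linear_retarder(0.3, 0.7) %*%
    linear_diattenuator(0.1, 0.2)
  f <- lc_decompose(unclass(M))
  expect_equal(f$Delta, 1 - mean(c(0.9, 0.9, 0.8)), tolerance = 1e-6)
  expect_equal(f$delta, 0.7, tolerance = 1e-6)
  expect_equal(f$theta, 0.3, tolerance = 1e-6)
  expect_equal(f$D, 0.2, tolerance = 1e-6)

  set.seed(31)
  for (i in 1:100) {
    p <- random_physical_mm(with_circular = TRUE)
    f <- lc_decompose(p$M)
    expect_equal(f$delta, p$delta, tolerance = 1e-6)
    expect_lt(axis_distance(f$theta, p$theta), 1e-6)
    expect_equal(f$D, p$d, tolerance = 1e-6)
    expect_equal(f$Delta, p$depol, tolerance = 1e-6)
  }
})

test_that("linear retardance: closed forms and circular non-leakage", {
  expect_equal(linear_retardance(diag(4)), 0)
  for (th in c(0, 0.4, 1.5)) {
    expect_equal(linear_retardance(linear_retarder(th, pi / 2)), pi / 2,
                 tolerance = 1e-12)
  }
  # a circular component must not leak into delta
  set.seed(8)
  for (i in 1:50) {
    th <- runif(1, 0, pi); de <- runif(1, 0.05, pi - 0.05)
    psi <- runif(1, -1, 1)
    mR <- linear_retarder(th, de) %*% circular_retarder(psi)
    expect_equal(linear_retardance(mR), de, tolerance = 1e-10)
  }
})

test_that("fast-axis azimuth: recovery, on-axis case, and undefined cutoff", {
  expect_equal(fast_axis_azimuth(linear_retarder(pi / 6, 1.0), 1.0), pi / 6,
               tolerance = 1e-10)
  expect_equal(fast_axis_azimuth(linear_retarder(0, 1.0), 1.0), 0,
               tolerance = 1e-10)
  expect_true(is.na(fast_axis_azimuth(linear_retarder(0.3, 0.005), 0.005)))
  set.seed(17)
  worst <- 0
  for (i in 1:500) {
    th <- runif(1, 0, pi); de <- runif(1, 0.05, pi - 0.05)
    m <- linear_retarder(th, de)
    worst <- max(worst, axis_distance(fast_axis_azimuth(m, de), th))
  }
  expect_lt(worst, 1e-8)
})

test_that("circular split: pure cases and reconstruction", {
  s <- split_circular(unclass(linear_retarder(0.5, 0.9)))
  expect_equal(s$psi, 0, tolerance = 1e-12)
  expect_equal(s$M_CR, unclass(circular_retarder(0)), tolerance = 1e-12)
  s2 <- split_circular(unclass(circular_retarder(0.4)))
  expect_equal(s2$psi, 0.4, tolerance = 1e-12)
  expect_equal(s2$M_LR, diag(4), tolerance = 1e-10)
  mix <- unclass(linear_retarder(0.8, 1.2) %*% circular_retarder(-0.3))
  s3 <- split_circular(mix)
  expect_equal(s3$M_LR %*% s3$M_CR, mix, tolerance = 1e-10)
})

test_that("theta is equivariant under sample-frame rotation, delta invariant", {
  set.seed(29)
  for (i in 1:50) {
    p <- random_physical_mm()
    al <- runif(1, -pi / 2, pi / 2)
    Mrot <- mm_rotation(al) %*% p$M %*% mm_rotation(-al)
    f <- lc_decompose(unclass(Mrot))
    expect_equal(f$delta, p$delta, tolerance = 1e-8)
    expect_lt(axis_distance(f$theta, (p$theta + al) %% pi), 1e-8)
  }
})

test_that("diattenuation and total retardance scalar extractors", {
  expect_equal(diattenuation(diag(4)), 0)
  expect_equal(diattenuation(unclass(linear_diattenuator(0, 0.3))), 0.3,
               tolerance = 1e-12)
  expect_equal(total_retardance(diag(4)), 0)
  expect_equal(total_retardance(unclass(linear_retarder(0.2, 1.3))), 1.3,
               tolerance = 1e-12)
})

test_that("ideal polarizer input is signaled, not silently decomposed", {
  f <- lc_decompose(unclass(linear_diattenuator(0.1, 1)))
  expect_false(f$ok)
  expect_match(f$reason, "polarizer")
})

test_that("image decomposition agrees with the single-matrix reference", {
  set.seed(61)
  n <- 40
  el <- array(0, c(n, 1, 4, 4))
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    p <- random_physical_mm(with_circular = TRUE)
    truth[[k]] <- p
    el[k, 1, , ] <- p$M / p$M[1, 1]
  }
  maps <- decompose_image(mueller_image(el, normalized = TRUE))
  for (k in seq_len(n)) {
    f <- lc_decompose(truth[[k]]$M)
    expect_equal(maps$delta[k, 1], f$delta, tolerance = 1e-10)
    expect_lt(axis_distance(maps$theta[k, 1], f$theta), 1e-10)
    expect_equal(maps$Delta[k, 1], f$Delta, tolerance = 1e-10)
    expect_equal(maps$D[k, 1], f$D, tolerance = 1e-10)
    expect_equal(maps$R[k, 1], f$R, tolerance = 1e-10)
  }
})

test_that("two-region phantom maps have the constructed region medians", {
  el <- array(0, c(10, 20, 4, 4))
  left <- cbind(rep(1:10, 10), rep(1:10, each = 10))
  for (r in 1:10) for (c in 1:20) {
    de <- if (c <= 10) 0.1 else 0.5
    el[r, c, , ] <- linear_retarder(0.9, de)
  }
  maps <- decompose_image(mueller_image(el, normalized = TRUE))
  expect_equal(median(maps$delta[, 1:10]), 0.1, tolerance = 1e-6)
  expect_equal(median(maps$delta[, 11:20]), 0.5, tolerance = 1e-6)
})

test_that("bad pixels are flagged without aborting the image", {
  el <- array(0, c(3, 3, 4, 4))
  for (r in 1:3) for (c in 1:3) el[r, c, , ] <- linear_retarder(0.2, 0.6)
  el[2, 2, , ] <- linear_diattenuator(0, 1)  # non-invertible diattenuator
  maps <- decompose_image(mueller_image(el, normalized = TRUE))
  expect_false(maps$valid[2, 2])
  expect_equal(sum(maps$valid), 8)
  expect_equal(maps$delta[1, 1], 0.6, tolerance = 1e-10)
})

test_that("delta map error shrinks when acquisition noise halves", {
  spec <- small_phantom_spec(seed = 19)
  truth <- generate_ground_truth(spec)
  rmse_at <- function(sigma) {
    st <- render_stack(truth, noise = noise_spec(gaussian_sd = sigma),
                       seed = 77)
    maps <- decompose_image(normalize_m11(mm_reconstruct(st)))
    fg <- truth$spot_id > 0 & maps$valid & is.finite(maps$delta)
    sqrt(mean((maps$delta[fg] - truth$delta[fg])^2))
  }
  expect_lt(rmse_at(0.0025), rmse_at(0.005))
})
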