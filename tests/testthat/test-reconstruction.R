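test_that("element formulas recover 2 * m_ij from the forward model", {
  # symbolic check of every coefficient row against the state-pair algebra
  set.seed(5)
  for (rep in 1:10) {
    m <- matrix(rnorm(16), 4, 4)   # arbitrary matrix: the algebra is linear
    I <- vapply(state_pairs(), function(pair)
      simulate_intensity(m, substr(pair, 1, 1), substr(pair, 2, 2)),
      numeric(1))
    co <- mm_element_formulas()
    for (i in 1:4) for (j in 1:4) {
      expect_equal(sum(co[[paste0("m", i, j)]] * I), 2 * m[i, j],
                   tolerance = 1e-12,
                   label = sprintf("element m%d%d", i, j))
    }
  }
})

test_that("identity sample reconstructs to a scaled identity", {
  st <- simulate_stack(diag(4), c(8, 8))
  mi <- mm_reconstruct(st)
  m <- pixel_matrix(mi, 3, 5)
  expect_equal(m / m[1, 1], diag(4), tolerance = 1e-12)
})

test_that("noiseless round trip: normalize(reconstruct(simulate)) == M / m11", {
  st <- simulate_stack(linear_retarder(0, pi / 2), c(4, 4))
  mi <- normalize_m11(mm_reconstruct(st))
  expect_equal(pixel_matrix(mi, 2, 2), unclass(linear_retarder(0, pi / 2)),
               tolerance = 1e-10)

  set.seed(99)
  worst <- 0
  for (i in 1:200) {
    M <- random_physical_mm(with_circular = TRUE)$M
    mi <- normalize_m11(mm_reconstruct(simulate_stack(M, c(1, 1))))
    worst <- max(worst, max(abs(pixel_matrix(mi, 1, 1) - M / M[1, 1])))
  }
  expect_lt(worst, 1e-10)
})

test_that("reconstruction is linear in the stack", {
  set.seed(21)
  m1 <- random_physical_mm()$M; m2 <- random_physical_mm()$M
  s1 <- simulate_stack(m1, c(3, 3)); s2 <- simulate_stack(m2, c(3, 3))
  mixed <- s1
  mixed$images <- Map(function(a, b) 0.3 * a + 1.7 * b,
                      s1$images, s2$images)
  r <- mm_reconstruct(mixed)
  r1 <- mm_reconstruct(s1); r2 <- mm_reconstruct(s2)
  expect_equal(r$elements, 0.3 * r1$elements + 1.7 * r2$elements,
               tolerance = 1e-12)
})

test_that("reconstruction error scales linearly with gaussian noise sd", {
  M <- random_physical_mm()$M
  err_at <- function(sigma) {
    st <- simulate_stack(M, c(64, 64),
                         noise = noise_spec(gaussian_sd = sigma), seed = 42)
    ref <- simulate_stack(M, c(64, 64))
    mi <- mm_reconstruct(st); mr <- mm_reconstruct(ref)
    sqrt(mean((mi$elements - mr$elements)^2))
  }
  r <- err_at(0.02) / err_at(0.005)
  expect_gt(r, 4 * 0.8)
  expect_lt(r, 4 * 1.2)
})

test_that("missing state pairs are reported by name", {
  st <- simulate_stack(diag(4), c(2, 2))
  st$images$RV <- NULL
  expect_error(mm_reconstruct(st), "RV")
})

test_that("normalize_m11 masks background and sets foreground m11 to 1", {
  # disc of tissue-like optics on a dark border
  el <- array(0, c(20, 20, 4, 4))
  M <- random_physical_mm()$M
  fg <- spot_mask(c(20, 20), 10, 10, 6)
  for (i in 1:4) for (j in 1:4) {
    img <- matrix(0.001, 20, 20)   # dark border below threshold
    img[fg] <- M[i, j]
    el[, , i, j] <- img
  }
  mi <- normalize_m11(mueller_image(el), background_threshold = 0.05)
  expect_equal(mi$mask, fg)
  expect_true(all(mi$elements[, , 1, 1][fg] == 1))
  expect_true(all(is.na(mi$elements[, , 1, 1][!fg])))
  # all-background image errors
  dark <- mueller_image(array(0, c(4, 4, 4, 4)))
  expect_error(normalize_m11(dark), "background")
})
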