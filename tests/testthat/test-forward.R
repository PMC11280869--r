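test_that("scalar intensities for the empty sample follow polarizer algebra", {
  expect_equal(simulate_intensity(diag(4), "H", "H"), 1)
  expect_equal(simulate_intensity(diag(4), "H", "V"), 0)
  expect_equal(simulate_intensity(diag(4), "H", "P"), 0.5)
  # quarter-wave plate at 0 degrees turns 45-degree linear into circular:
  # the R analyzer passes all or nothing depending on handedness
  I <- simulate_intensity(linear_retarder(0, pi / 2), "P", "R")
  expect_equal(abs(2 * I - 1), 1, tolerance = 1e-12)
})

test_that("a full stack enumerates exactly the 16 state pairs, once each", {
  st <- simulate_stack(diag(4), c(4, 4))
  expect_length(st$images, 16)
  expect_identical(names(st$images), state_pairs())
  expect_identical(sort(names(st$images)),
                   sort(as.vector(outer(c("H", "P", "V", "R"),
                                        c("H", "P", "V", "R"), paste0))))
  expect_true(all(vapply(st$images, function(x)
    identical(dim(x), c(4L, 4L)), TRUE)))
})

test_that("uniform-field stacks broadcast the scalar forward model", {
  m <- linear_retarder(pi / 6, 1.2)
  st <- simulate_stack(m, c(16, 16))
  for (pair in state_pairs()) {
    expected <- simulate_intensity(m, substr(pair, 1, 1), substr(pair, 2, 2))
    expect_true(all(st$images[[pair]] == expected))
  }
})

test_that("analyzer pair H+V recovers the total transmitted intensity", {
  set.seed(13)
  for (i in 1:20) {
    m <- random_physical_mm()$M
    for (g in c("H", "P", "V", "R")) {
      tot <- simulate_intensity(m, g, "H") + simulate_intensity(m, g, "V")
      p <- stokes_state(g)
      expect_equal(tot, as.numeric(c(1, 0, 0, 0) %*% m %*% p),
                   tolerance = 1e-12)
    }
  }
})

test_that("noisy simulation is seeded-deterministic and non-negative", {
  m <- linear_diattenuator(0.2, 0.3)
  ns <- noise_spec(gaussian_sd = 0.01)
  a <- simulate_stack(m, c(8, 8), noise = ns, seed = 7)
  b <- simulate_stack(m, c(8, 8), noise = ns, seed = 7)
  expect_identical(a, b)
  c1 <- simulate_stack(m, c(8, 8), noise = ns, seed = 8)
  expect_false(identical(a, c1))
  big <- simulate_stack(m, c(8, 8),
                        noise = noise_spec(gaussian_sd = 2), seed = 1)
  expect_true(all(vapply(big$images, min, 0) >= 0))
})

test_that("poisson shot noise converges to the mean at high counts", {
  m <- diag(4)
  st <- simulate_stack(m, c(32, 32),
                       noise = noise_spec(poisson_scale = 1e6), seed = 3)
  expect_equal(mean(st$images$HH), 1, tolerance = 1e-2)
})

test_that("stack TIFF round trips in both layouts", {
  m <- random_physical_mm()$M
  st <- simulate_stack(m, c(6, 5))
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "stack.tif")
  write_stack(st, f, layout = "multi")
  rt <- read_stack(f)
  expect_equal(rt$images, st$images, tolerance = 1e-7)
  d <- file.path(tmp, "frames")
  write_stack(st, d, layout = "files")
  rt2 <- read_stack(d)
  expect_equal(rt2$images, st$images, tolerance = 1e-7)
  # a missing frame is reported by name
  file.remove(file.path(d, "I_PV.tif"))
  expect_error(read_stack(d), "PV")
})
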