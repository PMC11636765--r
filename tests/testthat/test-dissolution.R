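test_that("dissolution rate honors its limiting cases", {
  expect_identical(dissolution_rate(5, 1, 100, 0.05, 0), 0)
  expect_identical(dissolution_rate(5, 10, 100, 0.1, 1.2), 0)   # at saturation
  expect_equal(dissolution_rate(8, 0, 500, 1, 1), 4)            # 8^(2/3) = 4
  # above saturation the rate is negative (precipitation), not clipped
  expect_lt(dissolution_rate(5, 60, 100, 0.5, 1), 0)
  expect_error(dissolution_rate(5, 1, 0, 0.05, 1), "volume")
})

test_that("dose scaling of z is cube-root multiplicative", {
  expect_equal(scale_z(0.7, 10, 10), 0.7)
  expect_equal(scale_z(1.0, 10, 80), 2.0)
  expect_equal(scale_z(0.0350, 10, 15), 0.040065, tolerance = 1e-5)
  zc <- scale_z(z_constant(1.24, "FaSSIF-V2"), 10, 15)
  expect_s3_class(zc, "z_constant")
  expect_true(zc$scaled)
  # composition: a -> b -> c equals a -> c
  expect_equal(scale_z(scale_z(0.5, 3, 7), 7, 11), scale_z(0.5, 3, 11))
  expect_error(scale_z(1, 0, 10), "positive")
})

test_that("forward dissolution conserves mass and saturates monotonically", {
  times <- seq(0.05, 6, by = 0.05)
  # saturation-limited: Cs*V = 2.465 mg < dose
  p <- simulate_dissolution(1.24, 0.00493, dose = 10, volume = 500, times)
  expect_true(all(diff(p$dissolved_mg) > -1e-12))
  expect_true(all(p$dissolved_mg <= 0.00493 * 500 + 1e-9))
  # exhaustion-limited: Cs*V = 50 mg > dose, dissolved -> dose
  q <- simulate_dissolution(50, 0.1, dose = 2, volume = 500,
                            times = c(0.5, 1, 2, 5))
  expect_true(all(q$dissolved_mg <= 2 + 1e-9))
  expect_gt(max(q$dissolved_mg), 0.999 * 2)
})

test_that("fit_z recovers the generating constant from a noiseless profile", {
  times <- c(5, 10, 15, 30, 45, 60) / 60
  prof <- simulate_dissolution(1.24, 0.00493, dose = 10, volume = 500, times)
  fit <- fit_z(prof, solubility = 0.00493)
  expect_true(fit$converged)
  expect_lt(abs(fit$z$value - 1.24) / 1.24, 0.01)
})

test_that("fit_z flags an all-zero profile as degenerate with z = 0", {
  flat <- dissolution_profile(c(0.1, 0.3, 0.5, 1), rep(0, 4), dose = 10,
                              volume = 500)
  expect_warning(fit <- fit_z(flat, solubility = 0.00493), "degenerate")
  expect_identical(fit$z$value, 0)
})

test_that("fit_z recovery error vanishes as measurement noise vanishes", {
  times <- c(5, 10, 15, 30, 45, 60) / 60
  clean <- fit_z(simulate_dissolution(1.24, 0.00493, dose = 10, volume = 500,
                                      times),
                 solubility = 0.00493)
  expect_lt(abs(clean$z$value - 1.24) / 1.24, 1e-3)
  # small additive noise relative to the dissolved signal (~0.03 mg at 1 h)
  zs <- vapply(1:20, function(s) {
    prof <- make_dissolution_profile(1.24, 0.00493, dose = 10, volume = 500,
                                     times, noise_sd = 0.002, seed = s)
    fit_z(prof, solubility = 0.00493)$z$value
  }, numeric(1))
  expect_lt(abs(median(zs) - 1.24) / 1.24, 0.10)
})
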