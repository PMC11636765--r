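test_that("dissolution generator is exact at zero noise and seed-deterministic", {
  times <- c(5, 10, 15, 30, 45, 60) / 60
  clean <- make_dissolution_profile(1.24, 0.00493, 10, 500, times)
  expect_identical(clean$dissolved_mg,
                   simulate_dissolution(1.24, 0.00493, 10, 500, times)$dissolved_mg)
  expect_false(clean$noisy)
  a <- make_dissolution_profile(1.24, 0.00493, 10, 500, times,
                                noise_sd = 0.01, seed = 11)
  b <- make_dissolution_profile(1.24, 0.00493, 10, 500, times,
                                noise_sd = 0.01, seed = 11)
  expect_identical(a$dissolved_mg, b$dissolved_mg)
  expect_true(a$noisy)
  expect_false(identical(
    a$dissolved_mg,
    make_dissolution_profile(1.24, 0.00493, 10, 500, times,
                             noise_sd = 0.01, seed = 12)$dissolved_mg))
})

test_that("dissolution noise realizes close to its nominal sd", {
  # high enough signal that truncation at 0 never bites
  times <- seq(0.5, 3, by = 0.5)
  clean <- simulate_dissolution(5, 0.1, 20, 500, times)$dissolved_mg
  res <- vapply(1:200, function(s) {
    make_dissolution_profile(5, 0.1, 20, 500, times, noise_sd = 0.4,
                             seed = s)$dissolved_mg - clean
  }, numeric(length(times)))
  expect_lt(abs(sd(as.vector(res)) - 0.4) / 0.4, 0.15)
})

test_that("observed-PK generator matches the truth model at zero noise", {
  scen <- synthetic_scenario("zetia", truth_variant = 4, noise_cv_pk = 0,
                             seed = 3, t_end = 30)
  st <- c(4.5, 11, 24)
  obs <- make_observed_pk(scen, st)
  truth <- attr(obs, "truth")
  expect_identical(obs$concentrations, plasma_concentration(truth, st))
  expect_identical(mape(obs, truth, st)$value, 0)
})

test_that("observed-PK noise is seed-deterministic and truth_sim reuse is exact", {
  scen <- synthetic_scenario("zetia", truth_variant = 4, noise_cv_pk = 0.1,
                             seed = 5, t_end = 30)
  st <- c(4.5, 11, 24)
  o1 <- make_observed_pk(scen, st)
  o2 <- make_observed_pk(scen, st, truth_sim = attr(o1, "truth"))
  expect_identical(o1$concentrations, o2$concentrations)
  expect_false(identical(
    o1$concentrations,
    make_observed_pk(synthetic_scenario("zetia", seed = 6, t_end = 30),
                     st)$concentrations))
})

test_that("product fixtures carry the measured constants and flag placeholders", {
  z <- product_fixture("zetia")
  expect_lt(abs(z$drug$free_fraction_fed - 0.169), 0.002)
  expect_equal(z$formulation$z_intestinal, 1.24)
  expect_equal(z$formulation$z_gastric, 4.75)
  expect_equal(z$formulation$cs_intestinal, 0.00493)
  m <- product_fixture("mobic")
  expect_identical(m$drug$free_fraction_fed, 1)
  expect_equal(m$formulation$z_intestinal, 0.0350)
  expect_true(m$systemic_is_synthetic && z$systemic_is_synthetic)
  # dose scaling kicks in when the in vivo dose differs from the 10 mg test
  m15 <- product_fixture("mobic", dose_vivo = 15)
  expect_equal(m15$formulation$z_intestinal, 0.040065, tolerance = 1e-5)
})

test_that("fixture -> noiseless profile -> fit recovers the fixture z within 1%", {
  fx <- product_fixture("zetia")
  times <- c(5, 10, 15, 30, 45, 60) / 60
  prof <- make_dissolution_profile(fx$formulation$z_intestinal,
                                   fx$formulation$cs_intestinal,
                                   dose = fx$dose_vitro, volume = 500, times)
  fit <- fit_z(prof, solubility = fx$formulation$cs_intestinal)
  expect_lt(abs(fit$z$value - fx$formulation$z_intestinal) /
              fx$formulation$z_intestinal, 0.01)
})
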