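test_that("exact standards are recovered perfectly", {
  std <- exact_standards(slope = 0.002, intercept = 0.10)
  curve <- fit_standard_curve(std)
  expect_equal(curve$slope, 0.002)
  expect_equal(curve$intercept, 0.10)
  expect_equal(curve$r_squared, 1)
  expect_equal(curve$valid_range, c(0, 100))
})

test_that("two standards define the line through both points", {
  curve <- fit_standard_curve(c(10, 50), c(0.3, 0.9))
  expect_equal(curve$slope, 0.6 / 40)
  expect_equal(curve$intercept, 0.3 - 10 * 0.6 / 40)
})

test_that("noisy standards match the normal-equations oracle", {
  for (s in 1:8) {
    conc <- seq(0, 80, 10)
    abs_ <- withr::with_seed(s, 0.012 * conc + 0.07 + rnorm(9, 0, 0.01))
    curve <- fit_standard_curve(conc, abs_)
    # closed-form least squares
    sx <- sum(conc); sy <- sum(abs_); sxx <- sum(conc^2)
    sxy <- sum(conc * abs_); n <- length(conc)
    slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
    intercept <- (sy - slope * sx) / n
    expect_equal(curve$slope, slope, tolerance = 1e-10)
    expect_equal(curve$intercept, intercept, tolerance = 1e-10)
    expect_equal(curve$r_squared, cor(conc, abs_)^2, tolerance = 1e-10)
  }
})

test_that("degenerate standard designs are rejected", {
  expect_error(fit_standard_curve(c(5, 5, 5), c(0.1, 0.2, 0.3)),
               "identical")
  expect_error(fit_standard_curve(c(1, 2), c(0.1)), "equal length")
})

test_that("curve inversion is exact, clamped and flagged", {
  curve <- fit_standard_curve(exact_standards(0.002, 0.10))
  expect_equal(invert_curve(curve, 0.10)$conc_ug_ml, 0)
  expect_false(invert_curve(curve, 0.10)$extrapolated)
  expect_equal(invert_curve(curve, 0.002 * 50 + 0.10)$conc_ug_ml, 50)
  # below-blank readings clamp to zero and flag when out of range
  low <- invert_curve(curve, 0.05)
  expect_equal(low$conc_ug_ml, 0)
  expect_true(low$extrapolated)
  high <- invert_curve(curve, 0.002 * 500 + 0.10)
  expect_true(high$extrapolated)

  flat <- curve
  flat$slope <- 0
  expect_error(invert_curve(flat, 0.2), "slope")
})

test_that("fit-predict-invert round trip is the identity on standards", {
  std <- exact_standards(0.0031, 0.083, conc = c(0, 5, 12, 30, 44, 75))
  curve <- fit_standard_curve(std)
  back <- invert_curve(curve, predict(curve, std$conc_ug_ml))$conc_ug_ml
  expect_equal(back, std$conc_ug_ml, tolerance = 1e-9)
})

test_that("inversion is strictly monotone for positive slope", {
  curve <- fit_standard_curve(exact_standards(0.01, 0.02))
  a <- seq(0.05, 1, by = 0.05)
  conc <- invert_curve(curve, a)$conc_ug_ml
  expect_true(all(diff(conc) > 0))
})

test_that("release profiles apply the closed-reservoir mass balance", {
  curve <- fit_standard_curve(exact_standards(0.01, 0.05))
  elu <- data.frame(well_id = "A", time_h = c(0, 1, 2),
                    absorbance = rep(0.05, 3))
  prof <- release_profile(elu, curve, reservoir_vol = 20)
  expect_equal(prof$cum_mass_ug, c(0, 0, 0))

  elu2 <- data.frame(well_id = "A", time_h = c(0, 1, 2),
                     absorbance = 0.05 + 0.01 * c(1, 4, 9))
  p20 <- release_profile(elu2, curve, reservoir_vol = 20)
  p40 <- release_profile(elu2, curve, reservoir_vol = 40)
  expect_equal(p40$cum_mass_ug, 2 * p20$cum_mass_ug)

  elu3 <- data.frame(well_id = "A", time_h = c(0, 1, 2),
                     absorbance = c(0.10, 0.30, 0.20))
  expect_warning(release_profile(elu3, curve, 20), "non-monotone")
})

test_that("noisy synthetic eluates recover the true release within 10%", {
  wells <- list(well_condition("ctrl", 0), well_condition("enz", 200))
  disc <- disc_spec()
  truth <- simulate_kinetics(wells, disc, duration = 20, step = 1 / 60,
                             seed = 21)
  curve <- fit_standard_curve(exact_standards(0.02, 0.05,
                                              conc = c(0, 5, 10, 20, 30,
                                                       40, 50)))
  elu <- simulate_eluates(truth, curve, times = c(0, 1, 2, 3, 17),
                          analyte = "pva", reservoir_vol = 20,
                          noise_sd = 0.005, seed = 22)
  prof <- suppressWarnings(release_profile(elu, curve, reservoir_vol = 20))
  for (w in c("ctrl", "enz")) {
    true_cum <- approx(truth$times, truth$cum_pva[, w],
                       xout = c(0, 1, 2, 3, 17))$y
    got <- prof$cum_mass_ug[prof$well_id == w]
    big <- true_cum >= 0.2 * disc$pva_load
    expect_true(any(big))
    expect_true(all(abs(got[big] - true_cum[big]) / true_cum[big] <= 0.10))
  }
})

test_that("enzyme-driven release exceeds passive release at the endpoint", {
  wells <- list(well_condition("ctrl", 0), well_condition("enz", 200))
  truth <- simulate_kinetics(wells, disc_spec(), duration = 20,
                             step = 1 / 60, seed = 31)
  curve <- fit_standard_curve(exact_standards(0.02, 0.05,
                                              conc = seq(0, 50, 10)))
  elu <- simulate_eluates(truth, curve, seed = 32)
  prof <- suppressWarnings(release_profile(elu, curve, 20))
  final <- tapply(prof$cum_mass_ug, prof$well_id,
                  function(x) x[length(x)])
  expect_gte(final[["enz"]], final[["ctrl"]])
  # both conditions show a nonzero early burst at the 1 h sample
  at1 <- prof$cum_mass_ug[prof$time_h == 1]
  expect_true(all(at1 > 0))
})
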