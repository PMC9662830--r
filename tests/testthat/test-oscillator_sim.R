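test_that("abrupt phase advance obeys the cosine amplitude law", {
  deltas <- c(0, 0.5, 1, 2, 4, 6, 10, 12)
  amps <- vapply(deltas, function(d) {
    s <- simulate_abrupt_shift(ensemble_config(shift_amount = d))
    post <- s$times >= 48   # whole cycles after the transition
    oscillation_amplitude(s$times[post], s$value[post], period = 24)
  }, numeric(1))
  expect_equal(amps / 100, abs(cos(pi * deltas / 24)), tolerance = 1e-6)
  # a half-period advance cancels the sum exactly
  expect_lt(amps[deltas == 12], 1e-9 * 100)
  # no shift leaves the signal identical to an unshifted ensemble
  s0 <- simulate_abrupt_shift(ensemble_config(shift_amount = 0))
  expect_equal(s0$value, 100 * cos(2 * pi * s0$times / 24), tolerance = 1e-9)
  expect_error(simulate_abrupt_shift(ensemble_config(n = 99)), "even")
  expect_error(simulate_abrupt_shift(ensemble_config(shift_amount = 30)),
               "shift_amount")
})

test_that("every shifted ensemble keeps the 24-h period", {
  for (d in c(0.5, 2, 6, 10)) {
    s <- simulate_abrupt_shift(ensemble_config(shift_amount = d))
    post <- s$times >= 36
    pt <- morlet_period_track(list(times = s$times[post],
                                   values = s$value[post]))
    expect_equal(as.numeric(names(which.max(table(pt$period[pt$kept])))), 24,
                 label = sprintf("shift %g h", d))
  }
})

test_that("gradual drift matches the Gaussian attenuation oracle", {
  # closed form E[cos(2*pi*eps/T)] for eps ~ N(0, sigma) vs brute force
  set.seed(77)
  for (sg in c(1, 4, 8, 12)) {
    mc <- mean(cos(2 * pi * rnorm(1e5, sd = sg) / 24))
    expect_lt(abs(mc - analytic_attenuation(sg)), 0.02)
  }
  # sigma solving the half-attenuation equation
  expect_equal(analytic_attenuation(4.497), 0.5, tolerance = 1e-3)

  # simulated ensembles: mean cos of the drawn phases at the final time,
  # averaged over seeds, reproduces the closed form
  fac <- vapply(1:50, function(s) {
    sim <- simulate_gradual_drift(
      ensemble_config(duration = 336, sigma_max = 6, seed = s),
      keep_phases = TRUE)
    mean(cos(2 * pi * sim$phases[, ncol(sim$phases)] / 24))
  }, numeric(1))
  se <- stats::sd(fac) / sqrt(length(fac))
  expect_lt(abs(mean(fac) - analytic_attenuation(6)), 4 * se + 0.01)
})

test_that("drift simulations are seed-deterministic and sigma = 0 never decays", {
  cfg <- ensemble_config(duration = 336, sigma_max = 6, seed = 5)
  a <- simulate_gradual_drift(cfg, keep_phases = TRUE)
  b <- simulate_gradual_drift(cfg, keep_phases = TRUE)
  expect_identical(a$phases, b$phases)
  expect_identical(a$value, b$value)
  frozen <- simulate_gradual_drift(
    ensemble_config(duration = 336, sigma_max = 0, seed = 5))
  expect_equal(max(abs(frozen$value)), 100, tolerance = 1e-9)
  expect_equal(min(tapply(abs(frozen$value),
                          floor(frozen$times / 24), max)), 100,
               tolerance = 1e-6)
  expect_error(simulate_gradual_drift(
    ensemble_config(sigma_max = -1)), "invalid sigma")
})

test_that("faster phase drift brings the amplitude half-life forward", {
  a50 <- vapply(c(6, 12), function(sm) {
    rep <- run_simulation("drift",
                          ensemble_config(duration = 336, sigma_max = sm,
                                          seed = 42))
    expect_equal(rep$scurve_peak$status, "ok")
    rep$scurve_peak$a50_time
  }, numeric(1))
  expect_lt(a50[2], a50[1])
  # both in the neighbourhood of the analytic half-attenuation times
  expect_lt(abs(a50[1] - 336 * 4.497 / 6), 60)
  expect_lt(abs(a50[2] - 336 * 4.497 / 12), 30)
})

test_that("cycle envelopes report per-cycle extremes", {
  cfg <- ensemble_config(n = 2, shift_amount = 0, duration = 96)
  s <- simulate_abrupt_shift(cfg)
  s$value <- s$value / 2          # single-oscillator amplitude
  env <- ensemble_amplitude_envelope(s)
  pk <- env[env$kind == "peak", ]
  expect_equal(nrow(pk), 4)
  expect_true(all(abs(pk$value - 1) < 1e-6))
  expect_true(all(abs(env$value[env$kind == "trough"] + 1) < 1e-6))
})
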