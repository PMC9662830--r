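#!/usr/bin/env Rscript
# Phase-coupling simulations of a 100-oscillator sinusoidal ensemble.
#
# Part 1 — abrupt phase advance: at 1.5 days, half the ensemble is advanced
# by 0-12 h. The summed signal's amplitude drops as |cos(pi*delta/24)| while
# its wavelet-ridge period stays at 24 h: desynchrony attenuates the
# population rhythm without changing its period, and a 12-h advance silences
# it entirely by destructive interference.
#
# Part 2 — gradual Gaussian phase drift: per-timepoint phase offsets with SD
# ramping to sigma_max over 14 days. The envelope decays as
# exp(-(2*pi*sigma(t)/24)^2/2); the fitted A50 arrives earlier at
# sigma_max = 12 than at 6 h.

library(lumirhythm)
dir.create("results", showWarnings = FALSE)

deltas <- c(0, 0.5, 1, 2, 4, 6, 10, 12)
abrupt <- do.call(rbind, lapply(deltas, function(d) {
  s <- simulate_abrupt_shift(ensemble_config(shift_amount = d))
  post <- s$times >= 48
  amp <- oscillation_amplitude(s$times[post], s$value[post], period = 24)
  pt <- morlet_period_track(list(times = s$times[s$times >= 36],
                                 values = s$value[s$times >= 36]))
  data.frame(shift_hr = d,
             amplitude = amp,
             amplitude_frac = amp / 100,
             analytic_frac = abs(cos(pi * d / 24)),
             ridge_period_hr = as.numeric(names(which.max(
               table(pt$period[pt$kept])))))
}))
write.csv(abrupt, "results/abrupt_shift_amplitudes.csv", row.names = FALSE)
cat("Abrupt phase advance of half the ensemble:\n")
print(abrupt, row.names = FALSE, digits = 6)
cat(sprintf("max |measured - analytic| amplitude fraction: %.2e\n",
            max(abs(abrupt$amplitude_frac - abrupt$analytic_frac))))
cat(sprintf("silencing advance: %g h; ridge period %s h for every advance\n\n",
            abrupt$shift_hr[abrupt$amplitude_frac < 1e-9],
            paste(unique(abrupt$ridge_period_hr), collapse = ", ")))

drift <- do.call(rbind, lapply(c(6, 12), function(sm) {
  rep <- run_simulation("drift",
                        ensemble_config(duration = 336, sigma_max = sm,
                                        seed = 1))
  sim <- simulate_gradual_drift(
    ensemble_config(duration = 336, sigma_max = sm, seed = 1),
    keep_phases = TRUE)
  final_factor <- mean(cos(2 * pi * sim$phases[, ncol(sim$phases)] / 24))
  data.frame(sigma_max_hr = sm,
             a50_hr = rep$scurve_peak$a50_time,
             analytic_half_attenuation_hr = 336 * 4.497 / sm,
             final_amplitude_factor = final_factor,
             analytic_final_factor = analytic_attenuation(sm))
}))
write.csv(drift, "results/drift_a50.csv", row.names = FALSE)
cat("Gradual Gaussian phase drift (one seeded ensemble each):\n")
print(drift, row.names = FALSE, digits = 4)
cat(sprintf("faster drift halves the amplitude earlier: A50(12) = %.0f h < A50(6) = %.0f h\n",
            drift$a50_hr[2], drift$a50_hr[1]))
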