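#' Configuration for oscillator-ensemble phase-coupling simulations
#'
#' An ensemble of N identical sinusoidal oscillators, summed to mimic a
#' population-level reporter signal. Two perturbations are modelled: an
#' abrupt phase advance of half the ensemble partway through the run, and a
#' gradual i.i.d. Gaussian phase drift whose standard deviation grows
#' linearly in time.
#'
#' @param n Number of oscillators; default 100 (must be even for
#'   half-ensemble shifts).
#' @param period Common oscillator period in hours; default 24.
#' @param sample_step Sampling step in hours; default 0.5.
#' @param duration Run length in hours; default 240 (10 days) for the abrupt
#'   protocol; use 336 (14 days) for the drift protocol.
#' @param shift_time Time of the abrupt shift in hours; default 36 (1.5 days).
#' @param shift_amount Phase advance applied to half the ensemble, hours.
#' @param sigma_max Final phase-drift SD in hours (reached at `duration`).
#' @param seed RNG seed for the drift protocol.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(n = 100, period = 24, sample_step = 0.5,
                            duration = 240, shift_time = 36,
                            shift_amount = 0, sigma_max = 6, seed = 1L) {
  if (abs(duration / sample_step - round(duration / sample_step)) > 1e-9)
    stop("duration must be a multiple of sample_step")
  structure(list(n = n, period = period, sample_step = sample_step,
                 duration = duration, shift_time = shift_time,
                 shift_amount = shift_amount, sigma_max = sigma_max,
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

new_summed_signal <- function(times, value, config, phases = NULL,
                              kind = "abrupt") {
  structure(list(times = times, value = value, config = config,
                 phases = phases, kind = kind),
            class = "summed_signal")
}

#' @export
as.data.frame.summed_signal <- function(x, ...) {
  data.frame(time_hr = x$times, value = x$value)
}

#' @export
print.summed_signal <- function(x, ...) {
  cat(sprintf("<summed_signal:%s> N=%d, %.0f h at %.2g h steps\n",
              x$kind, x$config$n, max(x$times), x$config$sample_step))
  invisible(x)
}

#' Abrupt phase advance of half an oscillator ensemble
#'
#' All N oscillators start in phase. At `shift_time`, half are advanced by
#' `shift_amount` hours while keeping the common period, so the summed
#' signal's post-shift amplitude is N * |cos(pi * shift / period)|: a
#' half-period advance (12 h on a 24 h clock) produces exact destructive
#' interference and a flat sum. Fully deterministic.
#'
#' @param config An [ensemble_config()]; `shift_amount` must lie in
#'   `[0, period]` and `n` must be even.
#' @param keep_phases Retain the per-oscillator phase matrix.
#' @return A `summed_signal` with `value[t] = sum_i cos(2*pi*(t + phi_i(t))/period)`.
#' @export
simulate_abrupt_shift <- function(config, keep_phases = FALSE) {
  if (config$n %% 2L != 0L) stop("N must be even")
  if (config$shift_amount < 0 || config$shift_amount > config$period)
    stop("shift_amount must lie in [0, period]")
  times <- seq(0, config$duration, by = config$sample_step)
  w <- 2 * pi / config$period
  shifted <- times >= config$shift_time
  half <- config$n / 2
  value <- half * cos(w * times) +
    half * cos(w * (times + ifelse(shifted, config$shift_amount, 0)))
  phases <- NULL
  if (keep_phases) {
    phases <- matrix(0, nrow = config$n, ncol = length(times))
    phases[seq_len(half), shifted] <- config$shift_amount
  }
  new_summed_signal(times, value, config, phases, kind = "abrupt")
}

#' Gradual Gaussian phase drift of an oscillator ensemble
#'
#' At each sample time t every oscillator's phase offset is drawn
#' independently from Normal(0, sigma(t)) with sigma(t) growing linearly
#' from 0 at t = 0 to `sigma_max` at `duration`. The expected summed signal
#' is `N * exp(-(2*pi*sigma(t)/period)^2 / 2) * cos(2*pi*t/period)`
#' (see [analytic_attenuation()]); the realised sum fluctuates around it.
#' Reproducible under `config$seed`. A random-walk variant
#' (`random_walk = TRUE`) accumulates increments instead, for exploration.
#'
#' @param config An [ensemble_config()] with `sigma_max >= 0`; use
#'   `duration = 336` for the standard 14-day protocol.
#' @param keep_phases Retain the per-oscillator phase offset matrix
#'   (n x timepoints, hours).
#' @param random_walk Accumulate phase increments instead of drawing i.i.d.
#'   offsets; default `FALSE` (i.i.d., analytically tractable).
#' @return A `summed_signal`.
#' @export
simulate_gradual_drift <- function(config, keep_phases = FALSE,
                                   random_walk = FALSE) {
  if (config$sigma_max < 0) stop("invalid sigma")
  times <- seq(0, config$duration, by = config$sample_step)
  nt <- length(times)
  w <- 2 * pi / config$period
  sigma_t <- config$sigma_max * times / config$duration
  set.seed(config$seed)
  eps <- matrix(stats::rnorm(config$n * nt), nrow = config$n)
  if (random_walk) {
    inc_sd <- sqrt(pmax(0, diff(c(0, sigma_t^2))))
    eps <- t(apply(sweep(eps, 2, inc_sd, `*`), 1, cumsum))
  } else {
    eps <- sweep(eps, 2, sigma_t, `*`)
  }
  value <- colSums(cos(w * (rep(times, each = config$n) + eps)))
  new_summed_signal(times, value, config,
                    phases = if (keep_phases) eps else NULL,
                    kind = "drift")
}

#' Cycle-by-cycle amplitude envelope of a summed ensemble signal
#'
#' Splits the signal into consecutive windows of one oscillator period and
#' records the maximum (peak) and minimum (trough) of each cycle with their
#' times, giving the amplitude envelope that S-curves are fitted to.
#'
#' @param signal A `summed_signal` spanning at least two periods.
#' @return An `extremum_series` data frame (`time`, `time_sd = 0`, `value`,
#'   `value_sd = 0`, `kind`, `n_merged = 1`); peak rows carry the cycle
#'   maxima, trough rows the minima.
#' @export
ensemble_amplitude_envelope <- function(signal) {
  P <- signal$config$period
  if (max(signal$times) - min(signal$times) < 2 * P)
    stop("signal must span at least two periods")
  cyc <- floor(signal$times / P)
  rows <- lapply(split(seq_along(signal$times), cyc), function(ii) {
    if (length(ii) < 4L) return(NULL)
    v <- signal$value[ii]
    tt <- signal$times[ii]
    data.frame(time = c(tt[which.max(v)], tt[which.min(v)]),
               time_sd = 0,
               value = c(max(v), min(v)),
               value_sd = 0,
               kind = c("peak", "trough"),
               n_merged = 1L)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$time), ]
  rownames(out) <- NULL
  class(out) <- c("extremum_series", "data.frame")
  out
}

#' Measure the amplitude of a steady oscillation from uniform samples
#'
#' Estimates the amplitude as `sqrt(2) * RMS` of the mean-removed signal over
#' the largest whole number of periods (half-open, so no sample is double
#' counted). For a pure sinusoid sampled uniformly with an integer number of
#' samples per period this is exact to machine precision, unlike the maximum
#' of the sampled values, which misses peaks falling between samples.
#'
#' @param times Uniform sample times, hours.
#' @param values Signal values.
#' @param period Oscillation period in hours; default 24.
#' @return The amplitude estimate (0 for a flat signal).
#' @export
oscillation_amplitude <- function(times, values, period = 24) {
  dt <- stats::median(diff(times))
  k <- floor((max(times) - min(times) + dt) / period)
  if (k < 1L) stop("need at least one full period")
  sel <- times >= min(times) & times < min(times) + k * period - dt / 2
  v <- values[sel]
  sqrt(2 * mean((v - mean(v))^2))
}

#' Expected amplitude attenuation under Gaussian phase dispersion
#'
#' For oscillator phases offset by Normal(0, sigma) hours on a period-T
#' cycle, the expected value of cos(2*pi*(t + eps)/T) is attenuated by
#' `exp(-(2*pi*sigma/T)^2 / 2)` — the characteristic function of the
#' Gaussian evaluated at the angular frequency. This closed form is the
#' oracle the drift simulation is validated against.
#'
#' @param sigma Phase SD in hours (vectorised).
#' @param period Oscillator period in hours; default 24.
#' @return Attenuation factor(s) in [0, 1].
#' @export
analytic_attenuation <- function(sigma, period = 24) {
  exp(-(2 * pi * sigma / period)^2 / 2)
}
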