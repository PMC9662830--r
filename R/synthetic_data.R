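#' Configuration for synthetic luminescence traces
#'
#' Describes a reporter-like trace: an exponentially decaying baseline plus a
#' sinusoid whose amplitude follows a decaying logistic envelope, with
#' optional count noise and an optional mid-course switch to an infradian
#' period. Ground truth travels with every generated trace so recovery tests
#' never have to re-infer it.
#'
#' @param period Oscillation period in hours, within [16, 72]; default 24.
#' @param initial_amplitude Oscillation amplitude at the start, counts;
#'   default 500.
#' @param baseline Baseline counts at t = 0; default 2000.
#' @param decay_timescale e-folding time of the baseline decay, hours;
#'   default 72 (signal decays over days as substrate is consumed).
#' @param envelope_a50 Inflection time of the logistic amplitude envelope,
#'   hours; default 144 (day 6 of a 9-day run).
#' @param envelope_slope Logistic steepness, 1/h; default 0.05.
#' @param noise One of `"none"`, `"gaussian"`, `"poisson"`.
#' @param noise_sd Gaussian noise SD in counts (ignored otherwise);
#'   default 0.2 * initial_amplitude.
#' @param switch_time,new_period Optional infradian switch: at `switch_time`
#'   the instantaneous period changes to `new_period` (phase-continuous).
#'   Both `NULL` (default) for no switch.
#' @param cadence Samples per hour; default 15 (4-min intervals).
#' @param duration Trace length in hours; default 216 (9 days).
#' @param n_replicates Replicates per condition; default 4 (plates of 15
#'   flies).
#' @param seed Master RNG seed.
#' @return A list of class `synth_trace_config`.
#' @export
synth_trace_config <- function(period = 24, initial_amplitude = 500,
                               baseline = 2000, decay_timescale = 72,
                               envelope_a50 = 144, envelope_slope = 0.05,
                               noise = c("none", "gaussian", "poisson"),
                               noise_sd = 0.2 * initial_amplitude,
                               switch_time = NULL, new_period = NULL,
                               cadence = 15, duration = 216,
                               n_replicates = 4, seed = 1L) {
  noise <- match.arg(noise)
  if (period < 16 || period > 72) stop("period must lie in [16, 72] h")
  if (duration < 2 * period) stop("duration must cover at least two periods")
  if (initial_amplitude < 0 || baseline < 0) stop("amplitudes must be >= 0")
  if (xor(is.null(switch_time), is.null(new_period)))
    stop("switch_time and new_period must be given together")
  structure(list(period = period, initial_amplitude = initial_amplitude,
                 baseline = baseline, decay_timescale = decay_timescale,
                 envelope_a50 = envelope_a50, envelope_slope = envelope_slope,
                 noise = noise, noise_sd = noise_sd,
                 switch_time = switch_time, new_period = new_period,
                 cadence = cadence, duration = duration,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "synth_trace_config")
}

#' Generate one synthetic luminescence trace with known ground truth
#'
#' `counts(t) = baseline * exp(-t / decay_timescale) + A(t) * sin(theta(t)) + noise`,
#' where `A(t) = initial_amplitude / (1 + exp(envelope_slope * (t - envelope_a50)))`
#' is the decaying logistic envelope and `theta(t)` integrates
#' `2*pi / P(t)` so the phase stays continuous across an infradian switch.
#' Counts are floored at zero (photon counts cannot be negative; with the
#' default parameters the floor is never reached).
#'
#' @param config A [synth_trace_config()].
#' @param replicate Replicate index recorded in metadata (and offsetting the
#'   seed); default 1.
#' @return A `raw_trace` whose `meta$ground_truth` records the generating
#'   period(s), envelope A50, and switch time.
#' @export
generate_luminescence_trace <- function(config, replicate = 1L) {
  t <- seq(0, config$duration, by = 1 / config$cadence)
  A <- config$initial_amplitude /
    (1 + exp(config$envelope_slope * (t - config$envelope_a50)))
  if (is.null(config$switch_time)) {
    theta <- 2 * pi * t / config$period
  } else {
    pre <- pmin(t, config$switch_time)
    post <- pmax(t - config$switch_time, 0)
    theta <- 2 * pi * (pre / config$period + post / config$new_period)
  }
  y <- config$baseline * exp(-t / config$decay_timescale) + A * sin(theta)
  if (config$noise != "none") {
    set.seed(derive_seed(config$seed, replicate))
    y <- switch(config$noise,
                gaussian = y + stats::rnorm(length(y), sd = config$noise_sd),
                poisson = stats::rpois(length(y), lambda = pmax(y, 0)))
  }
  raw_trace(t, pmax(y, 0),
            cadence = config$cadence,
            meta = list(replicate = replicate, n_flies = 15,
                        condition = "synthetic",
                        ground_truth = list(
                          period = config$period,
                          new_period = config$new_period,
                          switch_time = config$switch_time,
                          envelope_a50 = config$envelope_a50,
                          baseline = config$baseline,
                          initial_amplitude = config$initial_amplitude)))
}

# Per-replicate seeds derived deterministically from the master seed,
# kept inside 32-bit integer range.
derive_seed <- function(seed, replicate) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(replicate) * 104729) %%
               2147483647)
}

#' Generate a replicate set of synthetic traces
#'
#' n traces sharing ground truth but with independent noise (per-replicate
#' seeds derived from the master seed), each detrended and binned, bundled as
#' a `replicate_set` ready for [average_replicates()] or [run_analysis()].
#'
#' @param config A [synth_trace_config()].
#' @param degree Detrending polynomial degree; default 3.
#' @param bin_width Bin width in hours; default 0.5.
#' @param raw If `TRUE`, return the list of `raw_trace` objects instead of a
#'   binned `replicate_set`.
#' @return A `replicate_set` (or list of `raw_trace` when `raw = TRUE`) with
#'   the ground truth attached as attribute `"ground_truth"`.
#' @export
generate_replicate_set <- function(config, degree = 3, bin_width = 0.5,
                                   raw = FALSE) {
  if (config$n_replicates < 1L) stop("n_replicates must be >= 1")
  raws <- lapply(seq_len(config$n_replicates), function(i)
    generate_luminescence_trace(config, replicate = i))
  gt <- raws[[1]]$meta$ground_truth
  if (raw) {
    attr(raws, "ground_truth") <- gt
    return(raws)
  }
  binned <- lapply(raws, function(r)
    bin_trace(detrend_polynomial(r, degree = degree), bin_width = bin_width))
  set <- replicate_set(binned, condition = "synthetic")
  attr(set, "ground_truth") <- gt
  set
}

#' Configuration for synthetic locomotor activity counts
#'
#' Beam-break counts per 30-min bout with a 24-h bimodal rate profile
#' (morning and evening activity peaks as Gaussian bumps in circadian time),
#' Poisson-sampled per fly.
#'
#' @param morning_peak,evening_peak Circadian times (h) of the two activity
#'   peaks; defaults 0 and 12 (lights-on and lights-off anticipation).
#' @param peak_heights Relative heights of the two peaks; default c(1, 1.5).
#' @param peak_width SD of each Gaussian bump, hours; default 2.
#' @param rate_scale Mean counts per bin at a unit-height peak; default 20.
#' @param extra_period,extra_frac Optional slow multiplicative modulation
#'   `1 + extra_frac * sin(2*pi*t/extra_period)` of the rate (e.g. a 60-h
#'   infradian component); `extra_frac = 0` (default) disables it.
#' @param bin Bin width in hours; default 0.5.
#' @param duration Recording length in hours; default 216.
#' @param n_flies Number of flies; default 25.
#' @param seed RNG seed.
#' @return A list of class `synth_behavior_config`.
#' @export
synth_behavior_config <- function(morning_peak = 0, evening_peak = 12,
                                  peak_heights = c(1, 1.5), peak_width = 2,
                                  rate_scale = 20,
                                  extra_period = 60, extra_frac = 0,
                                  bin = 0.5, duration = 216,
                                  n_flies = 25, seed = 1L) {
  if (rate_scale < 0 || any(peak_heights < 0)) stop("rates must be >= 0")
  structure(list(morning_peak = morning_peak, evening_peak = evening_peak,
                 peak_heights = peak_heights, peak_width = peak_width,
                 rate_scale = rate_scale, extra_period = extra_period,
                 extra_frac = extra_frac, bin = bin, duration = duration,
                 n_flies = n_flies, seed = as.integer(seed)),
            class = "synth_behavior_config")
}

#' Generate synthetic locomotor beam-break counts
#'
#' @param config A [synth_behavior_config()].
#' @return A data frame with columns `time_hr` (bin mid-times),
#'   `beam_breaks`, `fly_id`; the rate function is attached as attribute
#'   `"rate"` (vector of per-bin expected counts).
#' @export
generate_locomotor_counts <- function(config) {
  t <- seq(config$bin / 2, config$duration - config$bin / 2, by = config$bin)
  circ <- t %% 24
  bump <- function(centre, height) {
    d <- pmin(abs(circ - centre), 24 - abs(circ - centre))
    height * exp(-d^2 / (2 * config$peak_width^2))
  }
  rate <- config$rate_scale *
    (bump(config$morning_peak, config$peak_heights[1]) +
       bump(config$evening_peak, config$peak_heights[2]))
  if (config$extra_frac != 0)
    rate <- rate * (1 + config$extra_frac * sin(2 * pi * t / config$extra_period))
  rate <- pmax(rate, 0)
  set.seed(config$seed)
  out <- do.call(rbind, lapply(seq_len(config$n_flies), function(f)
    data.frame(time_hr = t,
               beam_breaks = stats::rpois(length(t), rate),
               fly_id = f)))
  attr(out, "rate") <- rate
  out
}
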