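#' Morlet wavelet period-tracking configuration
#'
#' Parameters of the complex Morlet continuous wavelet transform used for
#' period tracking. The defaults are the calibrated values for 4-min
#' luminescence data: bandwidth 3, centre frequency 1, a 16-72 h period grid
#' in 1 h steps, and rejection of the lowest quarter of ridge confidences.
#'
#' @param bandwidth Morlet bandwidth parameter (variance of the Gaussian
#'   window in mother-wavelet time units); default 3.
#' @param central_frequency Morlet centre frequency in cycles per
#'   mother-wavelet time unit; default 1.
#' @param samples_per_hour Nominal sampling rate of the raw data; default 15
#'   (4-min intervals). Used only when a trace does not carry its own cadence.
#' @param dawn_offset Clock time of subjective dawn (hours); default 10.
#'   Metadata for plotting only.
#' @param period_min,period_max,period_step Period grid in hours; defaults
#'   16, 72, 1.
#' @param discard_fraction Fraction of timepoints with the lowest ridge
#'   confidence to flag as not kept; default 0.25.
#' @return A list of class `wavelet_config`.
#' @export
wavelet_config <- function(bandwidth = 3, central_frequency = 1,
                           samples_per_hour = 15, dawn_offset = 10,
                           period_min = 16, period_max = 72,
                           period_step = 1, discard_fraction = 0.25) {
  if (period_min >= period_max) stop("period_min must be below period_max")
  if (discard_fraction < 0 || discard_fraction >= 1)
    stop("discard_fraction must be in [0, 1)")
  structure(list(bandwidth = bandwidth,
                 central_frequency = central_frequency,
                 samples_per_hour = samples_per_hour,
                 dawn_offset = dawn_offset,
                 period_min = period_min, period_max = period_max,
                 period_step = period_step,
                 discard_fraction = discard_fraction),
            class = "wavelet_config")
}

#' Track the dominant oscillation period with a complex Morlet wavelet
#'
#' The continuous wavelet transform of the (mean-removed) signal is evaluated
#' on the scale grid mapped from the configured periods. The mother wavelet is
#' the complex Morlet
#' `psi(t) = (pi*fb)^(-1/2) * exp(2i*pi*fc*t) * exp(-t^2/fb)`
#' whose Fourier transform `exp(-pi^2*fb*(f - fc)^2)` peaks exactly at
#' `f = fc`, so scale `a` maps to period `a * dt / fc` with no empirical
#' correction: a pure sinusoid of grid period P attains maximum power at P.
#' The transform is computed in the frequency domain on a zero-padded signal
#' (no cone-of-influence masking). Power is normalised to [0, 1] over the
#' whole transform; per timepoint the ridge is the period of maximum
#' normalised power, and the timepoints whose ridge confidence falls in the
#' lowest `discard_fraction` are flagged not kept.
#'
#' @param trace A `binned_trace`, `raw_trace`, or list with `times`/`values`
#'   fields; sampling must be (near) uniform.
#' @param config A [wavelet_config()].
#' @param keep_power If `TRUE`, attach the full normalised power matrix
#'   (periods x times) as attribute `"power"`.
#' @return An object of class `period_track`: a data frame with columns
#'   `time` (h), `period` (best-fit period, h), `confidence` (normalised
#'   power in [0, 1]) and `kept` (logical).
#' @export
morlet_period_track <- function(trace, config = wavelet_config(),
                                keep_power = FALSE) {
  tv <- trace_times_values(trace)
  t <- tv$times
  y <- tv$values
  if (max(t) - min(t) < 2 * config$period_min) stop("trace too short")
  dt <- stats::median(diff(t))
  if (any(abs(diff(t) - dt) > 0.05 * dt))
    stop("wavelet period tracking requires uniform sampling")

  y <- y - mean(y)
  n <- length(y)
  npad <- 2^ceiling(log2(2 * n))
  ypad <- c(y, rep(0, npad - n))
  yhat <- stats::fft(ypad)
  freq <- (seq_len(npad) - 1) / npad          # cycles per sample
  freq[freq > 0.5] <- freq[freq > 0.5] - 1    # signed DFT frequencies

  periods <- seq(config$period_min, config$period_max,
                 by = config$period_step)
  fb <- config$bandwidth
  fc <- config$central_frequency
  scales <- fc * periods / dt                 # period (samples) * fc
  power <- matrix(0, nrow = length(periods), ncol = n)
  for (i in seq_along(scales)) {
    a <- scales[i]
    # analytic Morlet FT; flat (amplitude) normalisation across scales so a
    # unit sinusoid has the same peak response at every period and the ridge
    # of a pure sinusoid falls exactly on its grid period
    psi_hat <- exp(-pi^2 * fb * (a * freq - fc)^2)
    w <- stats::fft(yhat * psi_hat, inverse = TRUE) / npad
    power[i, ] <- Mod(w[seq_len(n)])^2
  }
  power <- power / max(power)

  ridge_idx <- apply(power, 2, which.max)
  conf <- power[cbind(ridge_idx, seq_len(n))]
  n_drop <- floor(config$discard_fraction * n)
  kept <- rep(TRUE, n)
  if (n_drop > 0L) kept[order(conf)[seq_len(n_drop)]] <- FALSE

  out <- data.frame(time = t, period = periods[ridge_idx],
                    confidence = conf, kept = kept)
  class(out) <- c("period_track", "data.frame")
  attr(out, "config") <- config
  if (keep_power) {
    dimnames(power) <- list(period = periods, NULL)
    attr(out, "power") <- power
  }
  out
}

# Pull times/values out of any supported trace container.
trace_times_values <- function(trace) {
  if (inherits(trace, "binned_trace"))
    list(times = trace$bin_mid_times, values = trace$values)
  else if (inherits(trace, "raw_trace"))
    list(times = trace$times, values = trace$counts)
  else if (inherits(trace, "detrended_trace"))
    list(times = trace$times, values = trace$signal)
  else if (inherits(trace, "summed_signal"))
    list(times = trace$times, values = trace$value)
  else if (!is.null(trace$times) && !is.null(trace$values))
    list(times = trace$times, values = trace$values)
  else stop("unsupported trace object")
}

#' Summarise a period track
#'
#' Mean and SD of the kept best-fit periods, optionally excluding infradian
#' fits: by convention, fits at or above 48 h separate "rhythmic" from
#' infradian/arrhythmic, so `restrict_below = 48` averages only the rhythmic
#' fits.
#'
#' @param track A `period_track`.
#' @param restrict_below Exclude kept points with period >= this value
#'   (hours), or `NULL` for no restriction.
#' @return List with `mean`, `sd`, `n`.
#' @export
summarize_period <- function(track, restrict_below = NULL) {
  p <- track$period[track$kept]
  if (!is.null(restrict_below)) p <- p[p < restrict_below]
  if (length(p) == 0L) stop("no rhythmic fits")
  list(mean = mean(p), sd = if (length(p) > 1L) stats::sd(p) else 0,
       n = length(p))
}

#' Detect the onset of arrhythmicity from a period track
#'
#' An oscillation is called arrhythmic when its wavelet best fit jumps from
#' the circadian (~24 h) band into the infradian (~60 h) band. The jump is
#' the first run of at least `run_length` consecutive kept points whose
#' period exceeds `threshold`; the onset time is the mean time of the (up to)
#' `window_points` kept points immediately preceding the jump. When the track
#' starts above threshold or fewer than `window_points` points precede the
#' jump, the available points are averaged and the result flagged.
#'
#' @param track A `period_track`.
#' @param threshold Period (h) separating circadian from infradian fits;
#'   default 48.
#' @param run_length Consecutive supra-threshold kept points required to call
#'   a jump (guards against single-point flicker); default 3.
#' @param window_points Number of preceding kept points averaged; default 25.
#' @return List of class `arrhythmia_onset` with `onset_time` (hours, or
#'   `NA` when no jump), `jump_time`, `n_averaged`, `at_start` flag, and the
#'   parameters used.
#' @export
detect_arrhythmia_onset <- function(track, threshold = 48, run_length = 3,
                                    window_points = 25) {
  k <- track[track$kept, , drop = FALSE]
  if (nrow(k) == 0L) stop("no kept points in track")
  above <- k$period > threshold
  jump <- NA_integer_
  if (nrow(k) >= run_length) {
    runs <- stats::filter(as.numeric(above), rep(1, run_length),
                          sides = 1)
    hits <- which(!is.na(runs) & runs == run_length)
    if (length(hits)) jump <- hits[1] - run_length + 1L
  }
  out <- list(onset_time = NA_real_, jump_time = NA_real_,
              n_averaged = 0L, at_start = FALSE,
              threshold = threshold, run_length = run_length,
              window_points = window_points)
  if (!is.na(jump)) {
    out$jump_time <- k$time[jump]
    if (jump == 1L) {
      lead <- seq_len(min(window_points, nrow(k)))
      out$onset_time <- mean(k$time[lead])
      out$n_averaged <- length(lead)
      out$at_start <- TRUE
    } else {
      pre <- seq.int(max(1L, jump - window_points), jump - 1L)
      out$onset_time <- mean(k$time[pre])
      out$n_averaged <- length(pre)
      out$at_start <- pre[1] == 1L && length(pre) < window_points
    }
  }
  class(out) <- "arrhythmia_onset"
  out
}

#' @export
print.arrhythmia_onset <- function(x, ...) {
  if (is.na(x$onset_time))
    cat("<arrhythmia_onset> no jump above",
        x$threshold, "h detected\n")
  else
    cat(sprintf(
      "<arrhythmia_onset> onset %.2f h (jump at %.2f h, %d points averaged%s)\n",
      x$onset_time, x$jump_time, x$n_averaged,
      if (x$at_start) ", at start" else ""))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of period distributions
#'
#' Compares two samples of period fits, optionally after restricting both to
#' a period range (e.g. the infradian 48-72 h band).
#'
#' @param a,b Numeric samples of period fits (hours).
#' @param range_filter Optional `c(min, max)`: keep only values in
#'   `[min, max]` in both samples before testing.
#' @return List with `D` (sup ECDF difference), `p` (asymptotic), and the
#'   filtered sample sizes `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b, range_filter = NULL) {
  if (!is.null(range_filter)) {
    a <- a[a >= range_filter[1] & a <= range_filter[2]]
    b <- b[b >= range_filter[1] & b <= range_filter[2]]
  }
  if (length(a) == 0L || length(b) == 0L)
    stop("empty sample after filter")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Range-restricted Lomb-Scargle periodogram
#'
#' Least-squares spectral power of a (possibly unevenly sampled) series on a
#' period grid restricted to `range`, as used for locomotor beam-break
#' counts. Power uses the standard least-squares normalisation
#' `P(f) = 1 - chi2(f) / chi2_ref`, where `chi2(f)` is the residual sum of
#' squares of the best-fitting sinusoid at frequency f and `chi2_ref` that of
#' the mean-only model, so `P` lies in [0, 1] and equals 1 for a noiseless
#' sinusoid at f.
#'
#' @param times Sample times in hours.
#' @param values Sample values (e.g. counts).
#' @param range Period search range `c(min, max)` in hours.
#' @param step Period grid step in hours; default 0.1.
#' @return List with `best_period` (h), `peak_power`, `degenerate` flag
#'   (constant input), and `periodogram` (data frame `period`, `power`).
#' @export
lomb_scargle_range <- function(times, values, range, step = 0.1) {
  if (length(times) < 8L) stop("need at least 8 samples")
  span <- diff(range(times))
  if (range[1] < 1 || range[2] > span)
    stop("period range must lie within [1, span]")
  periods <- seq(range[1], range[2], by = step)
  y <- values - mean(values)
  chi2_ref <- sum(y^2)
  if (chi2_ref < .Machine$double.eps) {
    pg <- data.frame(period = periods, power = 0)
    return(list(best_period = NA_real_, peak_power = 0,
                degenerate = TRUE, periodogram = pg))
  }
  power <- vapply(periods, function(P) {
    w <- 2 * pi / P
    # generalised LS with floating mean: project on {1, cos, sin}
    X <- cbind(1, cos(w * times), sin(w * times))
    r <- stats::lm.fit(X, y)$residuals
    1 - sum(r^2) / chi2_ref
  }, numeric(1))
  best <- which.max(power)
  list(best_period = periods[best], peak_power = power[best],
       degenerate = FALSE,
       periodogram = data.frame(period = periods, power = power))
}
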