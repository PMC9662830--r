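#' Run the full rhythm-analysis chain on a set of replicate traces
#'
#' Composes the standard chain — polynomial detrend, 30-min binning,
#' replicate averaging, sliding-window sinusoid extrema, S-curve / A50 fits
#' for peak and trough envelopes, Morlet wavelet period tracking, period
#' summaries (all fits and circadian-only), and arrhythmia-onset detection —
#' and returns everything in one report. Extrema are computed per replicate
#' and pooled; the wavelet runs on the replicate-averaged trace. Warnings
#' from skipped windows or flat envelopes are collected into the report,
#' never dropped.
#'
#' @param x Input traces: a `replicate_set` of binned traces, a list of
#'   `raw_trace` objects, a single `raw_trace`, or a character vector of CSV
#'   paths readable by [read_luminometer_csv()].
#' @param degree Detrending polynomial degree (ignored for pre-binned
#'   input); default 3.
#' @param bin_width Bin width in hours; default 0.5.
#' @param window,step,period_bounds,merge_tol Sinusoid-window parameters,
#'   see [fit_window_extrema()].
#' @param wavelet A [wavelet_config()].
#' @param restrict_below Period cutoff (h) for the "rhythmic-only" summary;
#'   default 48.
#' @param onset_threshold,onset_run,onset_window Arrhythmia-onset
#'   parameters, see [detect_arrhythmia_onset()].
#' @param csv_dialect,csv_time_unit Passed to [read_luminometer_csv()] when
#'   `x` is a character vector of paths.
#' @return An object of class `analysis_report`: list with `average`
#'   (binned mean trace with SEM), `extrema` (pooled `extremum_series`),
#'   `scurve_peak`, `scurve_trough`, `track` (`period_track`),
#'   `period_all`, `period_rhythmic` (summaries or NULL), `onset`,
#'   `warnings` (character), and `config` (all parameters).
#' @export
run_analysis <- function(x, degree = 3, bin_width = 0.5,
                         window = 48, step = 24,
                         period_bounds = c(16, 32), merge_tol = 6,
                         wavelet = wavelet_config(), restrict_below = 48,
                         onset_threshold = 48, onset_run = 3,
                         onset_window = 25,
                         csv_dialect = "luminometer",
                         csv_time_unit = "min") {
  if (is.character(x)) {
    if (length(x) == 0L) stop("no inputs")
    traces <- list()
    for (p in x) {
      got <- read_luminometer_csv(p, dialect = csv_dialect,
                                  time_unit = csv_time_unit)
      traces <- c(traces, if (inherits(got, "raw_trace")) list(got) else got)
    }
    x <- traces
  }
  if (inherits(x, "raw_trace")) x <- list(x)
  if (is.list(x) && !inherits(x, "replicate_set")) {
    if (length(x) == 0L) stop("no inputs")
    stopifnot(all(vapply(x, inherits, TRUE, "raw_trace")))
    binned <- lapply(x, function(r)
      bin_trace(detrend_polynomial(r, degree = degree), bin_width = bin_width))
    x <- replicate_set(binned)
  }
  stopifnot(inherits(x, "replicate_set"))

  warns <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  avg <- average_replicates(x)
  per_rep <- lapply(x$traces, function(tr) collect(
    fit_window_extrema(tr, window = window, step = step,
                       period_bounds = period_bounds,
                       merge_tol = merge_tol)))
  extrema <- pool_extrema(per_rep, merge_tol = merge_tol)
  sc_peak <- fit_scurve_a50(extrema, "peak")
  sc_trough <- fit_scurve_a50(extrema, "trough")
  if (sc_peak$status != "ok")
    warns <- c(warns, paste0("peak S-curve: ", sc_peak$status))
  if (sc_trough$status != "ok")
    warns <- c(warns, paste0("trough S-curve: ", sc_trough$status))

  track <- morlet_period_track(avg, config = wavelet)
  period_all <- summarize_period(track)
  period_rhythmic <- tryCatch(
    summarize_period(track, restrict_below = restrict_below),
    error = function(e) { warns <<- c(warns, conditionMessage(e)); NULL })
  onset <- detect_arrhythmia_onset(track, threshold = onset_threshold,
                                   run_length = onset_run,
                                   window_points = onset_window)

  structure(list(average = avg, extrema = extrema,
                 scurve_peak = sc_peak, scurve_trough = sc_trough,
                 track = track, period_all = period_all,
                 period_rhythmic = period_rhythmic, onset = onset,
                 warnings = warns,
                 config = list(degree = degree, bin_width = bin_width,
                               window = window, step = step,
                               period_bounds = period_bounds,
                               merge_tol = merge_tol, wavelet = wavelet,
                               restrict_below = restrict_below,
                               onset_threshold = onset_threshold,
                               onset_run = onset_run,
                               onset_window = onset_window,
                               n_replicates = length(x$traces))),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d replicate(s), %d bins\n",
              x$config$n_replicates, length(x$average$values)))
  if (!is.null(x$period_rhythmic))
    cat(sprintf("  period (<%g h fits): %.2f +/- %.2f h (n=%d)\n",
                x$config$restrict_below, x$period_rhythmic$mean,
                x$period_rhythmic$sd, x$period_rhythmic$n))
  cat(sprintf("  period (all kept fits): %.2f +/- %.2f h (n=%d)\n",
              x$period_all$mean, x$period_all$sd, x$period_all$n))
  for (k in c("scurve_peak", "scurve_trough")) {
    s <- x[[k]]
    lbl <- sub("scurve_", "", k)
    if (s$status == "ok")
      cat(sprintf("  %s A50: %.1f h\n", lbl, s$a50_time))
    else cat(sprintf("  %s A50: %s\n", lbl, s$status))
  }
  if (is.na(x$onset$onset_time)) cat("  arrhythmia onset: none\n")
  else cat(sprintf("  arrhythmia onset: %.1f h%s\n", x$onset$onset_time,
                   if (x$onset$at_start) " (at start)" else ""))
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Run a phase-coupling simulation and analyse its summed signal
#'
#' Runs the abrupt-shift or gradual-drift ensemble simulation and, by
#' default, pushes the summed signal through the same envelope and wavelet
#' machinery used for luminescence traces (the summed signal is already
#' uniformly sampled, so no detrending or binning is applied).
#'
#' @param kind `"abrupt"` or `"drift"`.
#' @param config An [ensemble_config()].
#' @param analyze Run envelope + wavelet analysis on the summed signal;
#'   default `TRUE`.
#' @param wavelet A [wavelet_config()] for the analysis stage.
#' @return List of class `simulation_report` with `signal`
#'   (`summed_signal`), `envelope` (`extremum_series`), `scurve_peak`,
#'   `scurve_trough`, `track`, `period_all`.
#' @export
run_simulation <- function(kind = c("abrupt", "drift"), config,
                           analyze = TRUE, wavelet = wavelet_config()) {
  kind <- match.arg(kind)
  signal <- switch(kind,
                   abrupt = simulate_abrupt_shift(config),
                   drift = simulate_gradual_drift(config))
  out <- list(signal = signal, kind = kind, config = config)
  if (analyze) {
    env <- ensemble_amplitude_envelope(signal)
    out$envelope <- env
    out$scurve_peak <- fit_scurve_a50(env, "peak")
    out$scurve_trough <- fit_scurve_a50(env, "trough")
    out$track <- morlet_period_track(signal, config = wavelet)
    out$period_all <- summarize_period(out$track)
  }
  class(out) <- "simulation_report"
  out
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf("<simulation_report:%s> N=%d, %.0f h\n",
              x$kind, x$config$n, x$config$duration))
  if (!is.null(x$period_all))
    cat(sprintf("  dominant period: %.2f +/- %.2f h\n",
                x$period_all$mean, x$period_all$sd))
  if (!is.null(x$scurve_peak) && x$scurve_peak$status == "ok")
    cat(sprintf("  peak-envelope A50: %.1f h\n", x$scurve_peak$a50_time))
  invisible(x)
}
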