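#' Construct a raw luminescence trace
#'
#' A `raw_trace` holds a uniformly sampled photon-count series with plate /
#' replicate / condition metadata. Times are hours since recording start;
#' the nominal cadence (samples per hour) is inferred from the median
#' inter-sample gap when not supplied.
#'
#' @param times Numeric vector of sample times in hours, strictly increasing.
#' @param counts Numeric vector of non-negative photon counts, same length.
#' @param cadence Samples per hour. Default `NULL` infers `1 / median(diff(times))`.
#' @param meta Named list of metadata. Recognised entries: `genotype`,
#'   `driver`, `plate`, `replicate`, `condition`, `n_flies`, and
#'   `dawn_offset` (clock time of subjective dawn in hours, default 10, i.e.
#'   10:00; used only for plotting/day shading, never in computation).
#' @return An object of class `raw_trace`: a list with elements `times`,
#'   `counts`, `cadence`, `meta`.
#' @export
raw_trace <- function(times, counts, cadence = NULL, meta = list()) {
  times <- as.numeric(times)
  counts <- as.numeric(counts)
  if (length(times) != length(counts))
    stop("times and counts must have equal length")
  if (length(times) < 2L) stop("no samples")
  if (any(diff(times) <= 0)) stop("unsorted timestamps")
  if (any(counts < 0)) stop("invalid counts")
  gap <- stats::median(diff(times))
  if (is.null(cadence)) cadence <- 1 / gap
  if (abs(gap - 1 / cadence) >= 0.1 / cadence)
    stop("median inter-sample gap inconsistent with cadence")
  if (is.null(meta$dawn_offset)) meta$dawn_offset <- 10
  structure(list(times = times, counts = counts, cadence = cadence,
                 meta = meta),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %d samples, %.1f h span, cadence %.3g/h\n",
              length(x$times), diff(range(x$times)), x$cadence))
  if (length(x$meta)) {
    keep <- setdiff(names(x$meta), "dawn_offset")
    if (length(keep))
      cat("  meta:", paste(sprintf("%s=%s", keep,
                                   vapply(x$meta[keep], format, "")),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a plate-luminometer CSV export
#'
#' Two dialects are supported. Dialect `"luminometer"` (an instrument-style
#' export): a time column followed by one count column per plate; each plate
#' column yields one trace. Dialect `"tidy"`: long format with columns
#' `time_hr`, `counts`, and optionally `plate`, `replicate`, `condition`.
#'
#' @param path Path to a CSV file with a header row and at least two data rows.
#' @param dialect `"luminometer"` or `"tidy"`.
#' @param time_unit For the luminometer dialect, unit of the first column:
#'   `"min"` or `"hours"`. Ignored for tidy input (always hours).
#' @param meta Metadata list applied to every returned trace (see
#'   [raw_trace()]); per-plate / per-replicate fields from the file are added.
#' @return A single `raw_trace` when the file holds one trace, otherwise a
#'   list of `raw_trace` objects (named by plate for the luminometer dialect).
#' @export
read_luminometer_csv <- function(path,
                                 dialect = c("luminometer", "tidy"),
                                 time_unit = c("min", "hours"),
                                 meta = list()) {
  dialect <- match.arg(dialect)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) < 2L) stop("no samples")

  if (dialect == "tidy") {
    need <- c("time_hr", "counts")
    if (!all(need %in% names(df)))
      stop("tidy dialect requires columns time_hr, counts")
    key_cols <- intersect(c("plate", "replicate", "condition"), names(df))
    if (length(key_cols) == 0L || nrow(unique(df[key_cols])) == 1L) {
      m <- meta
      for (k in key_cols) m[[k]] <- df[[k]][1]
      return(raw_trace(df$time_hr, df$counts, meta = m))
    }
    groups <- split(df, df[key_cols], drop = TRUE)
    out <- lapply(groups, function(g) {
      m <- meta
      for (k in key_cols) m[[k]] <- g[[k]][1]
      raw_trace(g$time_hr, g$counts, meta = m)
    })
    return(out)
  }

  times <- df[[1]]
  if (time_unit == "min") times <- times / 60
  plate_cols <- names(df)[-1]
  out <- lapply(plate_cols, function(pc) {
    m <- meta
    m$plate <- pc
    raw_trace(times, df[[pc]], meta = m)
  })
  names(out) <- plate_cols
  if (length(out) == 1L) out[[1]] else out
}

#' Write a trace to tidy CSV
#'
#' Round-trips through [read_luminometer_csv()] with `dialect = "tidy"`;
#' output is bit-stable given identical floating-point input (times and
#' values are written with full precision).
#'
#' @param trace A `raw_trace`, `detrended_trace` or `binned_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.raw_trace <- function(x, ...) {
  df <- data.frame(time_hr = x$times, counts = x$counts)
  for (k in intersect(c("plate", "replicate", "condition"), names(x$meta)))
    df[[k]] <- x$meta[[k]]
  df
}

#' Remove the slow luminescence decay with a polynomial fit
#'
#' Luciferase signal decays over days (substrate depletion, reporter
#' turnover); the oscillation rides on that baseline. The baseline is
#' estimated as an ordinary-least-squares polynomial of the whole series and
#' subtracted, leaving a zero-mean residual oscillation. No smoothing is
#' applied to the residual.
#'
#' @param trace A `raw_trace`.
#' @param degree Polynomial degree, 1-6 sensible; default 3 captures a
#'   smooth multi-day exponential-like decay without absorbing the ~24 h
#'   oscillation.
#' @param divide If `TRUE`, divide by the fitted baseline instead of
#'   subtracting it (multiplicative normalisation); the default subtracts.
#' @return An object of class `detrended_trace`: list with `times`, `signal`,
#'   `trend_coefficients` (intercept first), `degree`, `cadence`, `meta`.
#' @export
detrend_polynomial <- function(trace, degree = 3, divide = FALSE) {
  stopifnot(inherits(trace, "raw_trace"))
  degree <- as.integer(degree)
  if (degree < 0 || degree >= length(trace$times) - 1L)
    stop("invalid degree")
  t <- trace$times
  y <- trace$counts
  fit <- stats::lm(y ~ stats::poly(t, degree, raw = TRUE))
  trend <- as.numeric(stats::fitted(fit))
  signal <- if (divide) y / trend - 1 else y - trend
  structure(list(times = t, signal = signal,
                 trend_coefficients = unname(stats::coef(fit)),
                 degree = degree, divide = divide,
                 cadence = trace$cadence, meta = trace$meta),
            class = "detrended_trace")
}

#' @export
as.data.frame.detrended_trace <- function(x, ...) {
  data.frame(time_hr = x$times, signal = x$signal)
}

#' Average a detrended trace into fixed-width time bins
#'
#' Samples are assigned to half-open bins `[k*w, (k+1)*w)` anchored at t = 0;
#' for gapless 4-min data this gives a deterministic 8/7-sample alternation
#' per 30-min bin. Empty bins are dropped.
#'
#' @param trace A `detrended_trace` (or `raw_trace`, in which case raw counts
#'   are binned).
#' @param bin_width Bin width in hours; default 0.5.
#' @return An object of class `binned_trace`: list with `bin_mid_times`,
#'   `values` (per-bin means), `n_per_bin`, `sem` (0 where n = 1),
#'   `bin_width`, `meta`.
#' @export
bin_trace <- function(trace, bin_width = 0.5) {
  if (bin_width <= 0) stop("bin_width must be positive")
  t <- trace$times
  y <- if (inherits(trace, "raw_trace")) trace$counts else trace$signal
  idx <- floor(t / bin_width + 1e-9)
  ord <- sort(unique(idx))
  g <- match(idx, ord)
  n <- tabulate(g, nbins = length(ord))
  mean_y <- as.numeric(tapply(y, g, mean))
  sd_y <- as.numeric(tapply(y, g, stats::sd))
  sem <- ifelse(n > 1L, sd_y / sqrt(n), 0)
  structure(list(bin_mid_times = (ord + 0.5) * bin_width,
                 values = mean_y, n_per_bin = n, sem = sem,
                 bin_width = bin_width,
                 meta = if (!is.null(trace$meta)) trace$meta else list()),
            class = "binned_trace")
}

#' @export
as.data.frame.binned_trace <- function(x, ...) {
  data.frame(time_hr = x$bin_mid_times, value = x$values,
             n = x$n_per_bin, sem = x$sem)
}

#' @export
print.binned_trace <- function(x, ...) {
  cat(sprintf("<binned_trace> %d bins of %.2g h, span %.1f-%.1f h\n",
              length(x$values), x$bin_width,
              min(x$bin_mid_times), max(x$bin_mid_times)))
  invisible(x)
}

#' Bundle binned replicate traces of one condition
#'
#' @param traces List of `binned_trace` objects sharing bin width and
#'   alignment (e.g. four plates of 15 flies each).
#' @param condition Condition label.
#' @return An object of class `replicate_set`.
#' @export
replicate_set <- function(traces, condition = "condition") {
  if (inherits(traces, "binned_trace")) traces <- list(traces)
  if (length(traces) < 1L) stop("no inputs")
  stopifnot(all(vapply(traces, inherits, TRUE, "binned_trace")))
  w <- vapply(traces, `[[`, numeric(1), "bin_width")
  if (any(abs(w - w[1]) > 1e-12)) stop("grid mismatch")
  structure(list(traces = traces, condition = condition),
            class = "replicate_set")
}

#' Average replicates bin-by-bin
#'
#' Traces are trimmed to the common bin span (luminometer runs end unevenly)
#' and averaged per bin; the SEM is the across-replicate standard deviation
#' divided by sqrt(n).
#'
#' @param set A `replicate_set`.
#' @return A `binned_trace` whose `sem` is the across-replicate SEM and
#'   whose `n_per_bin` is the number of replicates.
#' @export
average_replicates <- function(set) {
  stopifnot(inherits(set, "replicate_set"))
  traces <- set$traces
  if (length(traces) == 1L) return(traces[[1]])
  w <- traces[[1]]$bin_width
  keys <- lapply(traces, function(tr) round(tr$bin_mid_times / w - 0.5))
  common <- Reduce(intersect, keys)
  if (length(common) == 0L) stop("grid mismatch")
  common <- sort(common)
  vals <- vapply(seq_along(traces), function(i) {
    m <- match(common, keys[[i]])
    traces[[i]]$values[m]
  }, numeric(length(common)))
  n <- length(traces)
  mean_v <- rowMeans(vals)
  sd_v <- apply(vals, 1, stats::sd)
  structure(list(bin_mid_times = (common + 0.5) * w,
                 values = mean_v, n_per_bin = rep(n, length(common)),
                 sem = sd_v / sqrt(n), bin_width = w,
                 meta = c(traces[[1]]$meta, list(condition = set$condition,
                                                 n_replicates = n))),
            class = "binned_trace")
}
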