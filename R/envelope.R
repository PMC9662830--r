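#' Extract oscillation peaks and troughs by sliding-window sinusoid fitting
#'
#' A sinusoid `y = A * sin(2*pi*t/T + phi) + c` is fitted by nonlinear least
#' squares to each 2-day window of the binned trace, advancing one day at a
#' time (each day fitted together with half a day on either side). The
#' analytic extrema of each fitted sinusoid inside its window are collected,
#' and extrema from overlapping windows that fall within `merge_tol` of each
#' other are averaged in both time and value, recording the spread and the
#' number merged.
#'
#' The period is constrained to `period_bounds` so a window cannot lock onto
#' a harmonic or an infradian component. Fits are initialised
#' deterministically from a linear harmonic regression at T = 24 h (which
#' gives the exact least-squares amplitude and phase for that period), so
#' repeated runs are identical. Non-convergent windows are skipped with a
#' warning; extrema are never fabricated.
#'
#' @param trace A `binned_trace` (or anything with `bin_mid_times`/`values`).
#' @param window Window length in hours; default 48.
#' @param step Window advance in hours; default 24.
#' @param period_bounds Allowed fitted period range in hours; default c(16, 32).
#' @param merge_tol Extrema from different windows closer than this (hours)
#'   are treated as the same peak/trough and averaged; default 6, half the
#'   minimum inter-extremum spacing on the short-period boundary.
#' @return An object of class `extremum_series`: a data frame with columns
#'   `time` (mean, h), `time_sd`, `value` (mean), `value_sd`,
#'   `kind` ("peak"/"trough"), `n_merged`.
#' @export
fit_window_extrema <- function(trace, window = 48, step = 24,
                               period_bounds = c(16, 32), merge_tol = 6) {
  t <- trace$bin_mid_times
  y <- trace$values
  span <- max(t) - min(t)
  if (span < window) stop("trace span shorter than fitting window")
  starts <- seq(min(t), max(t) - window + 1e-9, by = step)
  # keep the final day covered: add a window flush with the trace end when
  # the regular grid stops short of it
  if (max(starts) + window < max(t) - 1e-6)
    starts <- c(starts, max(t) - window)

  raw <- list()
  n_failed <- 0L
  for (ws in starts) {
    sel <- t >= ws & t < ws + window
    if (sum(sel) < 8L) next
    fit <- fit_sinusoid_window(t[sel], y[sel], period_bounds)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    raw[[length(raw) + 1L]] <-
      sinusoid_extrema(fit, ws, ws + window)
  }
  if (n_failed > 0L)
    warning(sprintf("%d window fit(s) did not converge and were skipped",
                    n_failed))
  if (length(raw) == 0L) stop("no extrema")
  pts <- do.call(rbind, raw)
  merge_extrema(pts, merge_tol)
}

# Least-squares sinusoid fit with bounded period, by profiling the residual
# sum of squares over the period: at fixed T the model is linear in
# (amplitude, phase, offset), so a coarse period grid plus golden-section
# refinement gives the global bounded optimum deterministically, with no
# gradient-based convergence failures. Returns list(A, T, phi, c) with
# A >= 0, or NULL when the fit is degenerate.
fit_sinusoid_window <- function(t, y, period_bounds) {
  harmonic <- function(T) {
    X <- cbind(1, sin(2 * pi * t / T), cos(2 * pi * t / T))
    f <- stats::lm.fit(X, y)
    list(rss = sum(f$residuals^2), coef = f$coefficients)
  }
  grid <- seq(period_bounds[1], period_bounds[2], by = 0.25)
  rss <- vapply(grid, function(T) harmonic(T)$rss, numeric(1))
  if (!all(is.finite(rss))) return(NULL)
  i <- which.min(rss)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  Tbest <- if (hi > lo)
    stats::optimize(function(T) harmonic(T)$rss, c(lo, hi))$minimum
  else grid[i]
  h <- harmonic(Tbest)$coef
  if (!all(is.finite(h))) return(NULL)
  A <- sqrt(h[2]^2 + h[3]^2)
  if (A < .Machine$double.eps^0.5 * max(1, stats::sd(y))) return(NULL)
  list(A = unname(A), T = Tbest, phi = atan2(h[3], h[2]), c = unname(h[1]))
}

# Analytic extrema of A*sin(2*pi*t/T + phi) + c inside [t0, t1].
sinusoid_extrema <- function(p, t0, t1) {
  # peaks where 2*pi*t/T + phi = pi/2 + 2k*pi; troughs at 3*pi/2 + 2k*pi
  times_at <- function(target) {
    k0 <- ceiling((t0 / p$T) - (target - p$phi) / (2 * pi))
    k1 <- floor((t1 / p$T) - (target - p$phi) / (2 * pi))
    if (k1 < k0) return(numeric(0))
    ((target - p$phi) / (2 * pi) + k0:k1) * p$T
  }
  pk <- times_at(pi / 2)
  tr <- times_at(3 * pi / 2)
  rbind(
    if (length(pk)) data.frame(time = pk, value = p$A + p$c, kind = "peak"),
    if (length(tr)) data.frame(time = tr, value = -p$A + p$c, kind = "trough"))
}

# Greedy single-pass clustering of window extrema, separately per kind.
merge_extrema <- function(pts, merge_tol) {
  out <- list()
  for (kd in c("peak", "trough")) {
    sub <- pts[pts$kind == kd, , drop = FALSE]
    if (nrow(sub) == 0L) next
    sub <- sub[order(sub$time), , drop = FALSE]
    grp <- integer(nrow(sub))
    g <- 1L
    grp[1] <- g
    centre <- sub$time[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$time[i] - centre > merge_tol) {
        g <- g + 1L
        centre <- sub$time[i]
      } else {
        centre <- mean(c(sub$time[grp == g], sub$time[i]))
      }
      grp[i] <- g
    }
    agg <- lapply(split(sub, grp), function(s) {
      data.frame(time = mean(s$time),
                 time_sd = if (nrow(s) > 1L) stats::sd(s$time) else 0,
                 value = mean(s$value),
                 value_sd = if (nrow(s) > 1L) stats::sd(s$value) else 0,
                 kind = kd, n_merged = nrow(s))
    })
    out[[kd]] <- do.call(rbind, agg)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$time), ]
  rownames(res) <- NULL
  class(res) <- c("extremum_series", "data.frame")
  res
}

#' Pool extremum series from several replicates
#'
#' Extrema are computed per replicate and then pooled: points of the same
#' kind within `merge_tol` across replicates are averaged in time and value,
#' mirroring per-peak replicate averaging with across-replicate spread.
#'
#' @param series_list List of `extremum_series`.
#' @param merge_tol Merge tolerance in hours; default 6.
#' @return A pooled `extremum_series`.
#' @export
pool_extrema <- function(series_list, merge_tol = 6) {
  pts <- do.call(rbind, lapply(series_list, function(s)
    data.frame(time = s$time, value = s$value, kind = s$kind)))
  merge_extrema(pts, merge_tol)
}

#' Fit an S-curve to a peak or trough envelope and locate its A50
#'
#' The amplitude-stability metric A50 is the time at which the oscillation
#' envelope falls halfway between its plateau values, read as the inflection
#' of a four-parameter logistic
#' `y(t) = bottom + (top - bottom) / (1 + exp(slope * (t - a50)))`
#' fitted by least squares to the extremum values over time. The slope is
#' unconstrained in sign so decay and growth are both representable; fits are
#' normalised so `top >= bottom`.
#'
#' @param series An `extremum_series`.
#' @param kind Which envelope to fit: `"peak"` or `"trough"`.
#' @param flatness Fraction of the point value range below which a fitted
#'   |top - bottom| is reported as no detectable decay; default 0.25.
#' @return An object of class `scurve_fit`: list with `top`, `bottom`,
#'   `a50_time`, `hill_slope`, `rss`, `n_points`, `status` in
#'   `"ok"`, `"no_decay"`, `"too_few_points"`. On a non-`ok` status the
#'   parameter fields are `NA`.
#' @export
fit_scurve_a50 <- function(series, kind = c("peak", "trough"),
                           flatness = 0.25) {
  kind <- match.arg(kind)
  sub <- series[series$kind == kind, , drop = FALSE]
  make <- function(status, top = NA_real_, bottom = NA_real_,
                   a50 = NA_real_, slope = NA_real_, rss = NA_real_)
    structure(list(top = top, bottom = bottom, a50_time = a50,
                   hill_slope = slope, rss = rss,
                   n_points = nrow(sub), kind = kind, status = status),
              class = "scurve_fit")
  if (nrow(sub) < 4L) return(make("too_few_points"))
  t <- sub$time
  y <- sub$value
  rng <- diff(range(y))
  if (rng < .Machine$double.eps^0.5 * max(1, max(abs(y))))
    return(make("no_decay"))
  # endpoint means give the plateau starts; midpoint time starts the a50
  nq <- max(2L, floor(length(y) / 4))
  y_early <- mean(y[seq_len(nq)])
  y_late <- mean(y[seq.int(length(y) - nq + 1L, length(y))])
  s0 <- if (y_early >= y_late) 4 / diff(range(t)) else -4 / diff(range(t))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + exp(slope * (t - a50))),
      start = list(top = max(y_early, y_late), bottom = min(y_early, y_late),
                   slope = s0 * 4, a50 = mean(range(t))),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(make("no_decay"))
  p <- as.list(stats::coef(fit))
  if (p$top < p$bottom) {  # same curve with plateaus swapped and slope flipped
    tmp <- p$top; p$top <- p$bottom; p$bottom <- tmp
    p$slope <- -p$slope
  }
  rss <- sum(stats::resid(fit)^2)
  if (abs(p$top - p$bottom) < flatness * rng) return(make("no_decay"))
  if (p$a50 < min(t) - 24 || p$a50 > max(t) + 24) return(make("no_decay"))
  make("ok", top = p$top, bottom = p$bottom, a50 = p$a50,
       slope = p$slope, rss = rss)
}

#' @export
print.scurve_fit <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("<scurve_fit:%s> A50 = %.2f h (top %.3g, bottom %.3g, slope %.3g, %d points)\n",
                x$kind, x$a50_time, x$top, x$bottom, x$hill_slope, x$n_points))
  else
    cat(sprintf("<scurve_fit:%s> status: %s (%d points)\n",
                x$kind, x$status, x$n_points))
  invisible(x)
}

#' @export
as.data.frame.scurve_fit <- function(x, ...) {
  data.frame(kind = x$kind, status = x$status, top = x$top,
             bottom = x$bottom, a50_time = x$a50_time,
             hill_slope = x$hill_slope, rss = x$rss, n_points = x$n_points)
}
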