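# Build a binned_trace directly from a function of time, bypassing the
# detrend/bin stages, for tests that target the fitting machinery alone.
make_binned <- function(f, duration = 216, bin_width = 0.5) {
  t <- seq(bin_width / 2, duration - bin_width / 2, by = bin_width)
  structure(list(bin_mid_times = t, values = f(t),
                 n_per_bin = rep(1L, length(t)),
                 sem = rep(0, length(t)),
                 bin_width = bin_width, meta = list()),
            class = "binned_trace")
}

# An extremum_series from explicit points.
make_extrema <- function(time, value, kind = "peak") {
  out <- data.frame(time = time, time_sd = 0, value = value, value_sd = 0,
                    kind = kind, n_merged = 1L)
  class(out) <- c("extremum_series", "data.frame")
  out
}

# A period_track from explicit periods (all kept unless stated).
make_track <- function(period, time = seq_along(period) * 0.5,
                       kept = rep(TRUE, length(period))) {
  out <- data.frame(time = time, period = period,
                    confidence = rep(1, length(period)), kept = kept)
  class(out) <- c("period_track", "data.frame")
  out
}

# Write a two-plate luminometer-style CSV (time in minutes) and return its path.
write_luminometer_fixture <- function(path, duration = 216, period = 24,
                                      seed = 1) {
  set.seed(seed)
  tmin <- seq(0, duration * 60 - 4, by = 4)
  th <- tmin / 60
  mk <- function() round(pmax(
    2000 * exp(-th / 72) + 400 * sin(2 * pi * th / period) +
      rnorm(length(th), sd = 20), 0))
  utils::write.csv(data.frame(time_min = tmin, plate1 = mk(), plate2 = mk()),
                   path, row.names = FALSE, quote = FALSE)
  path
}
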