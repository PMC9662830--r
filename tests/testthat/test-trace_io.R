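test_that("luminometer CSV reading converts minutes to hours and infers cadence", {
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_min = c(0, 4, 8), counts = c(10, 11, 12)),
                   p, row.names = FALSE)
  tr <- read_luminometer_csv(p, time_unit = "min")
  expect_s3_class(tr, "raw_trace")
  expect_equal(tr$times, c(0, 4, 8) / 60, tolerance = 1e-12)
  expect_equal(tr$cadence, 15)
  expect_equal(tr$counts, c(10, 11, 12))
})

test_that("a 9-day 4-min export yields 3240 samples and round-trips through tidy CSV", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_luminometer_fixture(p, duration = 216)
  traces <- read_luminometer_csv(p, time_unit = "min")
  expect_length(traces, 2)
  expect_length(traces[[1]]$times, 9 * 24 * 15)
  out <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(traces$plate1, out)
  back <- read_luminometer_csv(out, dialect = "tidy")
  expect_equal(back$times, traces$plate1$times)
  expect_equal(back$counts, traces$plate1$counts)
})

test_that("malformed luminescence files are rejected with specific errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_min,counts", p)
  expect_error(read_luminometer_csv(p), "no samples")
  utils::write.csv(data.frame(time_min = c(0, 8, 4), counts = c(1, 2, 3)),
                   p, row.names = FALSE)
  expect_error(read_luminometer_csv(p), "unsorted")
  utils::write.csv(data.frame(time_min = c(0, 4, 8), counts = c(1, -2, 3)),
                   p, row.names = FALSE)
  expect_error(read_luminometer_csv(p), "invalid counts")
})

test_that("polynomial detrending removes polynomial trends exactly", {
  t <- seq(0, 216, by = 1 / 15)
  const <- raw_trace(t, rep(500, length(t)))
  d <- detrend_polynomial(const, degree = 3)
  expect_lt(max(abs(d$signal)), 1e-8)

  cubic <- raw_trace(t, 1000 + 5 * t - 0.05 * t^2 + 1e-4 * t^3)
  d2 <- detrend_polynomial(cubic, degree = 3)
  expect_lt(sqrt(mean(d2$signal^2)), 1e-9 * sqrt(mean(cubic$counts^2)))

  expect_error(detrend_polynomial(const, degree = -1), "invalid degree")
})

test_that("detrending an exponential baseline preserves oscillation peak times", {
  t <- seq(0, 216, by = 1 / 15)
  y <- 1000 * exp(-t / 100) + 50 * sin(2 * pi * t / 24)
  d <- detrend_polynomial(raw_trace(t, y), degree = 3)
  true_peaks <- seq(6, 210, by = 24)
  for (tp in true_peaks) {
    sel <- abs(d$times - tp) <= 8
    found <- d$times[sel][which.max(d$signal[sel])]
    expect_lt(abs(found - tp), 0.5)
  }
  expect_lt(abs(mean(d$signal)), 1e-9 * stats::sd(y))
})

test_that("detrending is idempotent", {
  t <- seq(0, 216, by = 1 / 15)
  y <- 2000 * exp(-t / 72) + 300 * sin(2 * pi * t / 24) + 500
  d1 <- detrend_polynomial(raw_trace(t, y), degree = 3)
  shifted <- raw_trace(t, d1$signal - min(d1$signal))  # keep counts >= 0
  d2 <- detrend_polynomial(shifted, degree = 3)
  rel <- sqrt(mean((d2$signal - d1$signal)^2)) / sqrt(mean(d1$signal^2))
  expect_lt(rel, 1e-9)
})

test_that("binning assigns half-open bins with the 8/7 alternation and drops empty bins", {
  t <- seq(0, 216 - 1 / 15, by = 1 / 15)
  d <- structure(list(times = t, signal = t, meta = list()),
                 class = "detrended_trace")
  b <- bin_trace(d, bin_width = 0.5)
  expect_length(b$values, 9 * 48)
  expect_true(all(b$n_per_bin %in% c(7L, 8L)))
  # ramp: each bin mean equals the mean of its member timestamps
  for (i in c(1, 100, 432)) {
    lo <- (i - 1) * 0.5
    member <- t[t >= lo & t < lo + 0.5]
    expect_equal(b$values[i], mean(member), tolerance = 1e-12)
  }
  # constant signal: every bin value equal, SEM 0
  bc <- bin_trace(structure(list(times = t, signal = rep(100, length(t)),
                                 meta = list()),
                            class = "detrended_trace"))
  expect_true(all(abs(bc$values - 100) < 1e-12))
  expect_true(all(bc$sem == 0))
})

test_that("binning conserves the grand mean and the oscillation phase", {
  set.seed(3)
  t <- seq(0, 216 - 1 / 15, by = 1 / 15)
  y <- 300 * exp(-t / 90) * sin(2 * pi * t / 24) + rnorm(length(t), sd = 5)
  b <- bin_trace(structure(list(times = t, signal = y, meta = list()),
                           class = "detrended_trace"))
  expect_equal(sum(b$values * b$n_per_bin) / sum(b$n_per_bin), mean(y),
               tolerance = 1e-12)
  # argmax of the binned first cycle within one bin width of the true peak
  sel <- b$bin_mid_times < 24
  peak_bin <- b$bin_mid_times[sel][which.max(b$values[sel])]
  expect_lte(abs(peak_bin - 6), 0.5)
})

test_that("replicate averaging trims to the common span and propagates SEM", {
  mk <- function(v, n_bins = 10)
    structure(list(bin_mid_times = (seq_len(n_bins) - 0.5) * 0.5,
                   values = rep(v, n_bins), n_per_bin = rep(8L, n_bins),
                   sem = rep(0, n_bins), bin_width = 0.5, meta = list()),
              class = "binned_trace")
  # identical traces: mean equals the trace, SEM 0
  s4 <- replicate_set(list(mk(5), mk(5), mk(5), mk(5)))
  a4 <- average_replicates(s4)
  expect_true(all(a4$values == 5) && all(a4$sem == 0))
  expect_true(all(a4$n_per_bin == 4L))
  # two constants {0, 2}: mean 1, SEM sd/sqrt(2) = 1
  a2 <- average_replicates(replicate_set(list(mk(0), mk(2))))
  expect_true(all(a2$values == 1))
  expect_true(all(abs(a2$sem - 1) < 1e-12))
  # n = 4 convention: SEM = sd / 2
  vals <- c(1, 2, 3, 6)
  a <- average_replicates(replicate_set(lapply(vals, mk)))
  expect_equal(a$sem[1], stats::sd(vals) / 2, tolerance = 1e-12)
  # uneven spans trimmed to the shortest
  am <- average_replicates(replicate_set(list(mk(1, 10), mk(3, 6))))
  expect_length(am$values, 6)
})
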