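test_that("wavelet ridge sits on the true period across the whole 16-72 h grid", {
  t <- seq(0, 720, by = 0.5)
  for (P in c(16, 24, 37, 48, 60, 72)) {
    pt <- morlet_period_track(list(times = t, values = sin(2 * pi * t / P)))
    mode_kept <- as.numeric(names(which.max(table(pt$period[pt$kept]))))
    expect_equal(mode_kept, P, label = sprintf("period %d", P))
    # a 24-h rhythm should hold its ridge across the kept interior
    if (P == 24) expect_true(all(pt$period[pt$kept] == 24))
  }
})

test_that("bottom-fraction rejection keeps the configured share of points", {
  t <- seq(0, 432, by = 0.5)
  pt <- morlet_period_track(list(times = t, values = sin(2 * pi * t / 24)))
  expect_lte(abs(sum(pt$kept) - round(0.75 * nrow(pt))), 1)
  pt2 <- morlet_period_track(list(times = t, values = sin(2 * pi * t / 24)),
                             config = wavelet_config(discard_fraction = 0.5))
  expect_lte(abs(sum(pt2$kept) - round(0.5 * nrow(pt2))), 1)
  expect_true(all(pt$confidence >= 0 & pt$confidence <= 1))
})

test_that("a mid-course period switch moves the ridge from 24 h to 60 h", {
  t <- seq(0, 360, by = 0.5)
  y <- sin(2 * pi * (pmin(t, 120) / 24 + pmax(t - 120, 0) / 60))
  pt <- morlet_period_track(list(times = t, values = y))
  k <- pt[pt$kept, ]
  # clean circadian ridge well before the splice
  expect_true(all(k$period[k$time < 96] == 24))
  # infradian ridge after the splice, to within one grid step (the wavelet's
  # ~3-day time support at 60 h blends the boundary segments slightly)
  late_mode <- as.numeric(names(which.max(
    table(k$period[k$time > 193 & k$time < 312]))))
  expect_lte(abs(late_mode - 60), 1)
  expect_true(all(k$period[k$time > 193 & k$time < 312] > 48))
  # ridge crosses the 48-h line close to the splice (the crossing lags by up
  # to half the wavelet's time support), and the onset rule's backward
  # 25-point average pulls the estimate back toward the splice
  cross <- k$time[which(k$period > 48)[1]]
  expect_lt(abs(cross - 120), 36)
  onset <- detect_arrhythmia_onset(pt)
  expect_lt(abs(onset$onset_time - 120), 24)
})

test_that("period invariance: summed equal-period oscillators keep the common period", {
  t <- seq(0, 480, by = 0.5)
  set.seed(9)
  for (rep in 1:3) {
    phases <- runif(20, 0, 24)
    y <- rowSums(sapply(phases, function(p) cos(2 * pi * (t + p) / 24)))
    if (max(abs(y)) < 1) next   # near-complete cancellation carries no rhythm
    pt <- morlet_period_track(list(times = t, values = y))
    expect_equal(as.numeric(names(which.max(table(pt$period[pt$kept])))), 24)
  }
})

test_that("period summaries average kept fits with optional infradian exclusion", {
  tr <- make_track(c(20, 24, 28, 60, 64))
  s <- summarize_period(tr, restrict_below = 48)
  expect_equal(s$mean, 24)
  expect_equal(s$n, 3)
  all24 <- summarize_period(make_track(rep(24, 10)))
  expect_equal(all24$mean, 24)
  expect_equal(all24$sd, 0)
  expect_error(summarize_period(make_track(rep(60, 5)), restrict_below = 48),
               "no rhythmic fits")
  # discarded points never enter the summary
  tr2 <- make_track(c(24, 24, 70, 70), kept = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(summarize_period(tr2)$mean, 24)
})

test_that("arrhythmia onset averages the 25 kept points before the jump", {
  tr <- make_track(c(rep(24, 300), rep(60, 50)))
  on <- detect_arrhythmia_onset(tr)
  expect_equal(on$onset_time, mean((276:300) * 0.5))
  expect_equal(on$n_averaged, 25L)
  expect_false(on$at_start)

  none <- detect_arrhythmia_onset(make_track(rep(24, 100)))
  expect_true(is.na(none$onset_time))

  at_start <- detect_arrhythmia_onset(make_track(rep(60, 40)))
  expect_true(at_start$at_start)
  expect_equal(at_start$onset_time, mean((1:25) * 0.5))

  # single-point flicker below the run length is not a jump
  flick <- make_track(c(rep(24, 50), 60, rep(24, 50)))
  expect_true(is.na(detect_arrhythmia_onset(flick)$onset_time))
})

test_that("KS comparison of period distributions matches hand-computed D", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1, 3))$D, 0.5)
  # symmetry and range restriction
  a <- c(50, 55, 60, 70, 20)
  b <- c(49, 52, 66, 71, 30)
  expect_equal(ks_two_sample(a, b, c(48, 72))$D,
               ks_two_sample(b, a, c(48, 72))$D)
  expect_equal(ks_two_sample(a, b, c(48, 72))$n_a, 4)
  expect_error(ks_two_sample(c(20, 30), c(50, 60), c(48, 72)),
               "empty sample")
})

test_that("range-restricted Lomb-Scargle resolves circadian and infradian components", {
  t <- seq(0, 216, by = 0.5)
  y24 <- sin(2 * pi * t / 24)
  ls <- lomb_scargle_range(t, y24, c(16, 32))
  expect_lt(abs(ls$best_period - 24), 0.2)
  expect_gt(ls$peak_power, 0.9)
  # two-component mixture separated by the search range
  mix <- sin(2 * pi * t / 24) + 0.8 * sin(2 * pi * t / 60)
  expect_lt(abs(lomb_scargle_range(t, mix, c(16, 32))$best_period - 24), 0.2)
  expect_lt(abs(lomb_scargle_range(t, mix, c(48, 72))$best_period - 60), 1)
  # seeded white noise never reaches rhythmic power
  set.seed(41)
  noise <- rnorm(length(t))
  expect_lt(lomb_scargle_range(t, noise, c(16, 32))$peak_power, 0.2)
  # degenerate constant input is flagged with zero power
  flat <- lomb_scargle_range(t, rep(3, length(t)), c(16, 32))
  expect_true(flat$degenerate)
  expect_true(all(flat$periodogram$power == 0))
})
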