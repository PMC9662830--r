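---
title: "Methods: luminescence rhythm analysis and oscillator-ensemble simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: luminescence rhythm analysis and oscillator-ensemble simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumirhythm)
```

## The measurement problem

Long-term luciferase-reporter recordings from live animals (e.g. plates of
15 flies in a luminometer, one photon count every 4 minutes for ~9 days)
superimpose three things: a circadian oscillation of interest, a slow
multi-day decay of overall signal (substrate consumption, reporter
turnover), and counting noise. Two questions are asked of such traces: what
is the period of the oscillation, and how does it change over days; and how
quickly does the oscillation's *amplitude* decay — a stability metric for
the underlying cellular clocks, summarised as the **A50**, the time at which
the amplitude has fallen halfway between its plateau values.

The package implements the full chain for both questions, plus oscillator
ensemble simulations that show how *phase dispersion among cells* — rather
than any change in single-cell period — reproduces an amplitude collapse
with preserved period.

## The analysis chain

1. **Detrend** (`detrend_polynomial`). The baseline is an
   ordinary-least-squares polynomial of the *whole* series, subtracted from
   the counts; no smoothing is applied to the residual. Degree 3 by default:
   a cubic follows a smooth exponential-like decay over ~9 days closely, but
   cannot absorb a 24 h oscillation (9 days contain 9 cycles; a cubic has at
   most 2 interior extrema). Degrees 1–6 are accepted. Two open choices were
   resolved here: the fit is whole-series rather than per-day (a per-day fit
   would flatten genuine day-scale amplitude changes — the very signal A50
   measures), and the trend is *subtracted* (the oscillation rides
   additively on the baseline in the raw traces); a divide-by-trend variant
   sits behind `divide = TRUE` for data where the oscillation scales with
   the baseline.
2. **Bin** (`bin_trace`). Half-open 30-min bins anchored at the recording
   start; per-bin mean, count and SEM. For gapless 4-min data the bins
   alternate deterministically between 8 and 7 samples. Binning conserves
   the count-weighted grand mean exactly.
3. **Average replicates** (`average_replicates`). Traces are trimmed to the
   common bin span (runs end unevenly) and averaged per bin; the SEM is the
   across-replicate SD over √n.
4. **Extract the envelope** (`fit_window_extrema`). A sinusoid
   `A·sin(2πt/T + φ) + c` is fitted to each 48 h window, advancing 24 h at a
   time (each day fitted with half a day on either side; a final window
   flush with the trace end keeps the last day covered). The period is
   bounded to [16, 32] h so a window cannot lock onto a harmonic. The fit
   profiles the residual sum of squares over T — at fixed T the model is
   linear in (A, φ, c), so a coarse T grid plus golden-section refinement
   finds the bounded optimum deterministically, with no convergence
   failures and no random restarts. Analytic extrema of each window's
   sinusoid are collected; extrema from overlapping windows within
   `merge_tol = 6` h are averaged (x and y), with SD and multiplicity
   recorded. 6 h is half the minimum inter-extremum spacing at the T = 16 h
   bound, hence conservative at T ≈ 24. With several replicates, extrema
   are computed per replicate and pooled the same way (`pool_extrema`).
5. **Fit the S-curve and read the A50** (`fit_scurve_a50`). A
   four-parameter logistic in *time*,
   `y(t) = bottom + (top − bottom)/(1 + exp(slope·(t − a50)))`,
   is least-squares fitted to the peak (or trough) points; `a50` — the
   inflection — is the A50. The dose–response (log-concentration) form of
   the common 4PL is inappropriate on a linear time axis, so the slope is a
   plain rate with unconstrained sign (decay and growth both
   representable); fits are normalised to `top ≥ bottom`. Peaks and troughs
   are fitted separately. Fewer than 4 points gives status
   `too_few_points`; a fitted |top − bottom| under 25% of the point range,
   a non-convergent fit, or an inflection more than 24 h outside the data
   span gives `no_decay`. With noisy points a logistic will always fit
   *something*, so the flatness threshold is a coarse guard, not a
   significance test.
6. **Track the period** (`morlet_period_track`). Complex Morlet continuous
   wavelet transform with bandwidth 3 and centre frequency 1, evaluated on
   the 16–72 h period grid in 1 h steps. The transform is computed in the
   frequency domain — the Morlet's Fourier transform is the Gaussian
   `exp(−π²·fb·(af − fc)²)`, which peaks exactly at `f = fc/a` — on a
   zero-padded signal with no cone-of-influence masking. Per timepoint the
   *ridge* is the period of maximum power; power is normalised to [0, 1]
   over the whole transform and read as the fit confidence (a thresholded
   fraction, not a statistical confidence interval). The lowest 25% of
   ridge confidences are discarded, which in practice removes edges and
   transition bands. Scale-to-period mapping: with amplitude (flat)
   normalisation across scales a unit sinusoid has the same peak response
   at every period, so a noiseless sinusoid of any integer grid period
   recovers that period exactly; an energy (√a) normalisation would bias
   ridges toward longer periods by up to one grid step above ~60 h, which
   is why the flat convention is used.
7. **Summarise and detect arrhythmia** (`summarize_period`,
   `detect_arrhythmia_onset`). Period mean ± SD over kept points, optionally
   excluding fits ≥ 48 h (the conventional boundary between circadian and
   infradian fits). Arrhythmia onset: the first run of ≥ 3 consecutive kept
   points above 48 h marks the jump from ~24 h to ~60 h; the onset is the
   mean time of the 25 kept points immediately preceding it. The 3-point
   run requirement suppresses single-point flicker; when fewer than 25
   points precede the jump, the available points are averaged and the
   result flagged. The backward average deliberately leads the jump, which
   compensates the wavelet's forward smearing of the transition.
8. **Locomotor counts** (`lomb_scargle_range`). Beam-break counts per
   30-min bout are tested with a least-squares (Lomb–Scargle) periodogram
   on a period grid restricted to a band (circadian [16, 32] h or infradian
   [48, 72] h), at 0.1 h steps. Power is the fraction of variance explained
   by the best sinusoid at each period (`1 − χ²(f)/χ²_ref`), so it lies in
   [0, 1]; constant input is flagged degenerate with zero power.

`run_analysis` composes steps 1–7 and collects all warnings (skipped
windows, flat envelopes) into the report rather than dropping them; the
report is bit-reproducible given identical inputs and configuration.

## Ensemble simulations

`simulate_abrupt_shift`: 100 oscillators, common 24 h period, sampled every
0.5 h for 10 days, all in phase; at 1.5 days half are advanced by
Δ ∈ {0, 0.5, 1, 2, 4, 6, 10, 12} h. The summed signal's post-shift
amplitude is exactly `N·|cos(πΔ/T)|` (sum-to-product identity), so Δ = 12 h
annihilates it while the ridge period stays 24 h for every other Δ —
amplitude and period dissociate. Deterministic; the amplitude is measured
as √2 × RMS over whole cycles (`oscillation_amplitude`), which is exact on
the uniform grid, rather than as a sampled maximum.

`simulate_gradual_drift`: at each timepoint each oscillator's phase offset
is drawn i.i.d. from Normal(0, σ(t)), σ ramping linearly from 0 to
`sigma_max` over 14 days. The i.i.d. reading (taken literally from the
protocol) makes the realised sum jagged but analytically tractable: the
expected attenuation is the Gaussian characteristic function
`exp(−(2πσ/T)²/2)` (`analytic_attenuation`), the oracle all drift tests
compare against. A random-walk variant (`random_walk = TRUE`) is available
for exploration but has no closed-form envelope. Per-cycle envelope
extremes (`ensemble_amplitude_envelope`) feed the same S-curve machinery as
the luminescence pipeline; the fitted A50 arrives roughly twice as early at
`sigma_max` = 12 h as at 6 h. The "increments of 0.5 hr" in the protocol is
read as the sampling step, consistent with zero phase difference at t = 0.

## The synthetic generator: what it emulates, and what it does not

`generate_luminescence_trace` builds
`counts(t) = baseline·e^(−t/τ) + A(t)·sin(θ(t)) + noise`, with A(t) a
decaying logistic (top = initial amplitude, inflection = envelope A50) and
θ(t) integrating 2π/P(t) so the phase is continuous across an optional
period switch (24 h → 60 h). Defaults: baseline 2000 counts decaying with
τ = 72 h, amplitude 500 counts, A50 at 144 h (day 6 of a 9-day run),
Gaussian noise at 20% of the initial amplitude, 4 replicates of nominal 15
flies, 4-min cadence. The additive combination mirrors the
subtract-detrend convention; a multiplicative variant corresponds to
`divide = TRUE`. Ground truth travels with every trace, so recovery tests
never re-infer it.

Switch-detection runs use `envelope_a50 = 240` h on a 240-h trace: a period
jump is only observable while the oscillation still has amplitude, so the
envelope is kept alive through the 120-h switch. Combining a fully decayed
envelope with a late switch would make the jump undetectable by
construction, which tests nothing about the detector.

What the generator does **not** emulate: photomultiplier dark counts,
plate cross-talk, luciferin-uptake dependence on feeding, inter-fly
heterogeneity within a plate, or non-stationary noise. Passing recovery
tests therefore demonstrates correctness of the *analysis machinery* under
realistic signal shapes, not robustness to every artefact of real
recordings; real instrument exports should still be inspected after
detrending.

`generate_locomotor_counts` draws per-bin Poisson counts around a bimodal
24 h rate profile (morning/evening activity bumps), optionally modulated by
a slow infradian component, for the Lomb–Scargle band tests.

## Numerical choices and degenerate inputs

- Window sinusoid fits: period profiled on a 0.25 h grid then refined;
  windows whose best harmonic amplitude is at numerical zero are skipped
  with a warning (never fabricated extrema); an all-flat trace raises
  "no extrema".
- Wavelet: signal is mean-removed and zero-padded to the next power of two
  ≥ 2n; no edge masking — the bottom-25% confidence rejection is what
  removes edge-dominated points in practice. The kept fraction is
  `n − floor(0.25·n)`, within one point of 75%.
- Logistic fits: Levenberg–Marquardt (minpack.lm) from deterministic
  endpoint-mean initialisation; no random restarts anywhere in the package.
- Binning floors `t/width` with a 1e−9 guard so samples landing exactly on
  a bin boundary go to the right-hand bin on every platform.
- KS comparisons use the asymptotic two-sample test; ties in period grids
  are tolerated (the statistic is computed on ECDFs).
- Seeds: every stochastic generator takes an explicit seed; per-replicate
  seeds are derived from the master seed by a fixed affine map modulo
  2^31 − 1.

## Problem sizes

The test and validation suites run at the protocol's native scales: 9–10
day traces at 4-min cadence (3240 samples) for pipeline runs, 57-period
wavelet grids on 0.5-h-binned series, 50-seed Monte-Carlo batches for the
recovery and drift studies, and 200 randomised envelopes for the A50
property. A full pipeline run takes well under a second, so the batches
complete in tens of seconds.

## Known limitations

- The wavelet transition between two periods is smeared by the Morlet's
  time support (≈ ±3 days at a 60 h period with bandwidth 3): on a
  noiseless splice the ridge crosses 48 h only ~1.3 days after the true
  switch. The onset rule's backward 25-point average compensates most of
  this; under the study's noisy 4-replicate conditions the onset lands
  within ±12 h of the true switch in all 50 validation runs.
- "Confidence" is normalised wavelet power, not a coverage statement; no
  significance bands are attached to ridges, and no multitaper or χ²
  rhythm tests are provided.
- The A50 presumes a sigmoidal envelope; envelopes that rebound or decay
  non-monotonically will fit poorly (large RSS) rather than being rejected
  outright.
- Behavioural peak classification (morning vs evening anticipation) is out
  of scope; the envelope machinery can be applied to binned activity, but
  peaks are not labelled.
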