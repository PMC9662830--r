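# lumirhythm

Rhythm analysis for long-term in vivo bioluminescence reporter recordings,
and oscillator-ensemble simulations of clock desynchrony.

Luciferase reporters driven by clock-gene promoters let the circadian
oscillation of a tissue be read out for days from live animals — e.g.
plates of flies in a luminometer, one photon count every 4 minutes over 9
days, four replicate plates per condition. Two quantities summarise such a
trace: the oscillation **period** over time, and the **A50** — the time at
which oscillation amplitude has fallen halfway between its plateaus, a
stability metric for the underlying tissue clock. `lumirhythm` implements
the full chain from instrument CSV to those numbers, and the simulations
showing that *phase dispersion* across a cell population collapses the
summed amplitude without changing its period.

## What the package computes

Given replicate count series \(y_r(t)\):

1. **Detrend**: subtract an OLS polynomial \(P_d(t)\) (default \(d = 3\))
   fitted to the whole series — the slow decay of signal over days.
2. **Bin**: 30-min half-open bins; mean, n, SEM per bin; then average
   replicates bin-wise (SEM = SD/√n).
3. **Envelope**: fit \(A\sin(2\pi t/T + \varphi) + c\), \(T \in [16,32]\) h,
   to each 48 h window advancing by 24 h; collect the fitted sinusoids'
   analytic extrema; merge matching extrema across windows/replicates.
4. **A50**: least-squares 4-parameter logistic
   \(y(t) = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/(1 + e^{s(t - \mathrm{A50})})\)
   through the peak (or trough) values; the inflection is the A50.
5. **Period track**: complex Morlet CWT (bandwidth 3, centre frequency 1)
   on the 16–72 h period grid, 1 h steps; per timepoint the ridge is the
   period of maximum normalised power; the lowest 25% of ridge confidences
   are discarded. Summaries exclude infradian fits (≥ 48 h) on request;
   the arrhythmia onset is the mean time of the 25 kept points before the
   ridge's first sustained jump above 48 h.
6. **Locomotor counts**: range-restricted Lomb–Scargle periodogram
   (variance-explained normalisation, power in [0, 1]).
7. **Simulations**: 100 sinusoidal oscillators summed; an abrupt advance of
   half the ensemble by Δ attenuates the sum by \(|\cos(\pi\Delta/T)|\)
   (Δ = 12 h silences it) while the wavelet ridge stays at 24 h; gradual
   Gaussian phase drift (σ ramping over 14 days) dampens the envelope as
   \(e^{-(2\pi\sigma(t)/T)^2/2}\).

Synthetic generators (`synth_trace_config`, `generate_replicate_set`,
`generate_locomotor_counts`) produce traces with known ground truth, so
every stage has parameter-recovery tests without any recorded data.

## Worked example

```r
library(lumirhythm)
cfg <- synth_trace_config(noise = "gaussian", seed = 7)  # 24 h rhythm, A50 144 h
report <- run_analysis(generate_replicate_set(cfg))
print(report)
```

```
<analysis_report> 4 replicate(s), 433 bins
  period (<48 h fits): 24.00 +/- 0.00 h (n=325)
  period (all kept fits): 24.00 +/- 0.00 h (n=325)
  peak A50: 139.4 h
  trough A50: 172.1 h
  arrhythmia onset: none
```

The generator's truth was a 24 h period with the amplitude envelope
inflecting at 144 h: the wavelet ridge recovers the period exactly on the
1 h grid (325 kept timepoints), and the peak-envelope A50 lands at 139.4 h,
within the few-hour accuracy expected at 20% noise. No ridge jump above
48 h occurs, so no arrhythmia onset is reported.

The analysis drivers under `analysis/` run the three studies end to end and
write their tables to `results/`:

- `01_phase_coupling_sims.R` — abrupt-shift amplitude law (matches
  \(|\cos(\pi\Delta/24)|\) to ~1e−15; only Δ = 12 h silences the sum; ridge
  24 h throughout) and the drift A50 comparison (σ = 12 h halves the
  amplitude roughly twice as early as σ = 6 h).
- `02_pipeline_validation.R` — 50-seed recovery study: median period error
  ~0.17 h, median A50 error ~4 h, period-switch onset within ±12 h in all
  runs.
- `03_luminescence_demo.R` — the worked example above plus a locomotor
  Lomb–Scargle demo, with all intermediate tables serialised.

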