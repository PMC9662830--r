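Package: lumirhythm
Title: Circadian Rhythm Analysis of In Vivo Bioluminescence Reporter Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for long-term luciferase-reporter luminescence
    recordings from live animals: polynomial baseline detrending, 30-minute
    binning and replicate averaging, sliding-window sinusoid fitting to extract
    oscillation peaks and troughs, four-parameter logistic (S-curve) fits of
    the peak/trough envelopes yielding the A50 amplitude-stability metric,
    complex Morlet wavelet period tracking over the 16-72 hour band with
    confidence-based rejection and arrhythmia-onset detection, and a
    range-restricted Lomb-Scargle periodogram for locomotor activity counts.
    Also includes phase-coupling simulations of sinusoidal oscillator
    ensembles (abrupt half-ensemble phase advance and gradual Gaussian phase
    drift) with an analytic attenuation oracle, and synthetic trace generators
    with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
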