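---
title: "Methods: analysing slow electrochemical oscillations in proteinoid-quantum-dot networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing slow electrochemical oscillations in proteinoid-quantum-dot networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protodyn)
```

## The system and the signals

Proteinoids — thermal protein-like polymers formed by heating amino acids —
self-assemble in water into microspheres and toroids. Conjugated to
semiconductor quantum dots (QDs) they form hybrid networks that exhibit
spontaneous, very slow electrochemical oscillations: potentials of tens to
hundreds of millivolts varying on time scales of tens of seconds
(dominant components around 0.02–0.11 Hz), recorded at 1 Hz over periods
of days. `protodyn` implements the full signal-analysis chain such
recordings call for:

1. **Preprocessing** (`read_timeseries`, `interpolate_common_axis`,
   `subtract_baseline`, `iqr_outlier_flags`): recordings arrive as
   two-column CSVs; missing cells are interpolated, recordings are
   aligned onto the axis of the longest series, and the mean of the
   first 10 s is taken as the resting baseline.
2. **Descriptive oscillation statistics** (`summarize_oscillation`):
   moments, quartiles, peak-to-peak amplitude (defined as max − min),
   and the dominant frequency from the averaged periodogram.
3. **Spectral analysis** (`estimate_psd`, `fit_psd_slope`,
   `spectrogram`, `total_energy`, `msc`, `cross_correlation`): Welch
   power spectral density, log–log power-law exponent, short-time
   Fourier spectrogram with total-energy integration, magnitude-squared
   coherence between recordings or between a recording and a stimulus.
4. **Coherence metrics** (`shannon_entropy`, `qfi`, `qfi_curve`,
   `hilbert_analysis`): binned Shannon entropy of the voltage
   distribution, a variance-based quantum Fisher information (QFI)
   proxy, and Hilbert envelope/phase analysis.
5. **Stimulus encoding** (`stimulus_program`, `stimulus_waveform`,
   `decode_waveform`, `modulate_response`): ASCII text as a binary
   pulse train and the multiplicative amplitude-modulation response
   model.
6. **Electrochemical models** (`fit_exponential_decay`,
   `randles_impedance`, `eis_summary`, `memory_from_autocorrelation`,
   `fit_dynamic_decay`, `early_late_ttest`): square-wave voltammetry
   kinetics, Randles equivalent circuit, and capacitance memory.
7. **Boolean logic extraction** (`binarize_features`, `gate_panel`) and
   **toroid morphometry** (`rim_thickness`, `morphometry_table`).
8. **Orchestration** (`run_pipeline`): a declarative config drives
   preprocess → stats → spectral → coherence metrics end to end and
   emits versioned JSON reports.

## Models and estimators

### Baseline and amplitude conventions

The resting baseline is the mean of the first 10 s of the recording
(ignoring missing samples); the correction is idempotent. Peak-to-peak
**amplitude is max − min** of the series. This range definition is fixed
by the data layout the summary table mirrors: the tabulated amplitudes
equal max − min of the tabulated extrema for both the bare-polymer and
conjugate recordings. The **amplification factor** between two systems is
the plain ratio of their amplitudes.

### Welch PSD, slope fit and spectrogram

All spectral estimates share one engine: Hann-tapered, 50%-overlapping
segments, each linearly detrended, one-sided scaling such that
`sum(psd) * df` equals the variance of the tapered, detrended signal
(Parseval within 5%). Defaults: segment length 1024 samples (frequency
resolution ≈ 0.001 Hz at 1 Hz sampling) for PSD and spectrogram;
`min(4096, 2^floor(log2(n/4)))` for dominant-frequency peak-picking so at
least ~8 segments average. The taper and overlap are our choice — they
are the standard pairing that keeps Parseval tight while suppressing
leakage at the steep (β ≈ 3–4) spectra these recordings show.

The spectral exponent is the OLS slope of `log10(PSD)` on `log10(f)`
over a fit band, default **0.01–0.5 Hz**; the reported `stderr` is the
OLS standard error of the slope coefficient. The spectrogram converts
segment PSDs to dB re 1 (unit)²/Hz with a −120 dB floor guarding
zero-power cells; `total_energy` is the `df·dt`-weighted Riemann sum of
the linear-scale grid.

Magnitude-squared coherence uses cross- and auto-spectra from the same
segmentation. A single segment would give MSC ≡ 1 identically, so at
least two segments are required; with `m` independent segments the
expected bias floor for unrelated signals is ≈ 1/m, which the tests
check.

### Entropy, QFI proxy, Hilbert analysis

Entropy uses a 50-bin histogram over `[min, max]`; probabilities are
counts over n (not density values — density × binwidth is the
probability, and entropy of raw densities would not be scale invariant);
the result is in bits (`log2`). The estimate is invariant under affine
transforms because the edges move with the data.

The QFI proxy is the classical surrogate
`F_Q = 4 · Var(V) · S(f)` with `S(f) = 1/(2πf)²`. It is homogeneous in
the variance and falls as `f^-2`; it is *not* a quantum-state
computation, only a frequency-sensitivity statistic. When several
experiments are compared, every curve is normalized by the **single
global maximum across the compared set**, so the normalized peaks equal
the variance ratios `var_i / max_j var_j` exactly, independent of the
frequency grid. This normalization is fixed by the published normalized
peaks, which coincide with the variance ratios of the published standard
deviations (0.617 = (80.69/102.72)², 0.444 = (68.42/102.72)²). We note a
documented oddity: descriptions of such QFI curves sometimes speak of
values "rising" with frequency, but `S(f)` is strictly decreasing in
`f`; the package implements the formula and the monotonicity tests
assert the decreasing behaviour.

Hilbert analysis forms the discrete analytic signal by FFT (zeroing the
negative frequencies), giving the amplitude envelope and the unwrapped
instantaneous phase. The phase variance is computed on the *linearly
detrended* unwrapped phase: for any oscillation the raw phase grows
linearly at `2πf0` and its variance would otherwise measure only the
recording length.

### Stimulus encoding and response modulation

A message is transmitted one character at a time: 8 bits MSB-first
(fixed by the worked encodings `'T' → 01010100`, `'o' → 01101111`), one
10 s pulse slot per bit at 5 V (bit 1) or 0 V (bit 0), then a 10 s pause.
The pause follows *every* character including the last, which makes the
total-duration formula `N · (8·pulse + pause)` exact; one character
occupies 90 s, an effective input frequency of 1/90 ≈ 0.0111 Hz. The
decoder thresholds each slot mean at `(v_high+v_low)/2` and treats an
exact tie as a format error rather than guessing. The response model is
multiplicative amplitude modulation,
`output(t) = natural(t) · (1 + k · V_input(t))`.

### Electrochemical fits

Exponential decays (peak current vs SWV pulse frequency
`I = I0·e^{-αf}`; capacitance vs time `C = C0·e^{-kt}`; autocorrelation
vs lag `R = A·e^{-lag/τ} + C`) are fitted by Levenberg–Marquardt
nonlinear least squares with log-linear initialization and bounded
restarts; the characteristic scale `1/rate` (cut-off frequency `f_c` or
memory duration `τ`) is reported alongside, and `rate · characteristic
= 1` exactly. The dynamic capacitance model is stated in the literature
as `dC/dt = −k(C−C0)` with solution `C0·e^{-kt}`; these are
inconsistent (the printed solution solves `dC/dt = −kC`), and the
package fits the solution form, which is what the printed parameters
describe. The autocorrelation uses the biased (divide-by-n) estimator
over lags up to n/4 — the standard choice for decay-fitting stability.

The Randles forward model is
`Z(ω) = Rs + Rct/(1 + jωRctCdl) + W/√(jω)`; with `W = 0` the Nyquist
curve is a semicircle of diameter `Rct` with apex at the relaxation
frequency `f0 = 1/(2πRctCdl)`, identities the tests verify to 1e-9.
`eis_summary` reports means, SDs and normal-theory 95% CIs of Z′, Z″,
log10|Z| and phase; the magnitude is reported explicitly as log10 Ω
(some summaries print a bare "mean |Z|" that is dimensionally a log).
The early/late comparison is a **pooled-variance** two-sample t-test
(variance homogeneity is part of the reported protocol), two-sided, with
`delta = mean(late) − mean(early)`.

### Boolean gates

Features are binarized per family (SWV currents; capacitances) with the
rule **value ≥ 75th-percentile threshold → 1**; the 25th-percentile
threshold is carried as provenance only, because the worked examples
only ever switch on the high threshold. Thresholds are either supplied
explicitly or computed as linear-interpolation percentiles of a
reference list. The panel over the quintuple (A..E) evaluates NOT per
input, AND, OR, their complements, and parity: XOR is the left-fold
`(((A≠B)≠(C≠D))≠E)` — equal to the sum-of-bits parity — and XNOR is its
negation ("even number of true inputs"), resolving the ambiguous
precedence of the XNOR expression in favour of the tabulated semantics.
We deliberately take explicit thresholds and states rather than
recomputing them from the three printed currents: the printed
75th/25th thresholds are not the percentiles of those three values, and
one tabulated state (20 Hz, 169.01 μA, tabulated 0 despite exceeding
160.71) contradicts the threshold rule; the package reproduces the
tabulated logic outputs from the stated states and flags rather than
guesses the original feature-to-state rule.

### Morphometry

Rim thickness is `(outer − cavity)/2` per particle; the table aggregates
*per-record* derived quantities (mean of per-particle rims, not the rim
of mean diameters — the two differ in the published table, indicating
per-particle computation). Cavity/outer ratio and optional aspect ratio
are summarized the same way.

## The synthetic-data generator

Raw multi-day recordings are impractical to ship, so every stage is
exercised on seeded synthetic data with the statistical structure the
analysis assumes:

- `gen_colored_noise`: spectral synthesis — Gaussian Fourier
  coefficients scaled by `f^(-β/2)`, DC bin zeroed, inverse FFT,
  rescaled to a target SD. The one-sided PSD follows `f^(-β)` in
  expectation *exactly*, which makes slope-recovery tests sharp.
  Synthesis in the Fourier domain was chosen over AR filtering because
  its invariants are simpler and unbiased across the whole band.
- `gen_oscillation`: baseline + linear drift + sinusoid + colored
  noise. Defaults are the recording conditions the analysis targets:
  1 Hz sampling, dominant frequency 0.063 Hz (mid-band of the observed
  0.03–0.11 Hz), ~325 mV peak-to-peak, ~24 mV baseline, β = 3.5 noise
  (the observed slopes span ≈ −3.1 to −3.8). Drift is linear — the real
  traces show slow trends but no stated drift law.
- `gen_decay_series` and `gen_randles_spectrum`: the forward models of
  the SWV/capacitance fits and the impedance summaries.

What the generator does **not** emulate: regime switches between active
and quiescent phases, non-stationary amplitude envelopes, electrode
artefacts, and any mechanistic electrochemistry (redox cycling, charge
trapping). Passing tests therefore demonstrate estimator correctness on
signals with the assumed structure, not robustness to every pathology of
real electrode data.

## Numerical choices and degenerate inputs

- Quantiles everywhere use the linear-interpolation convention
  (`stats::quantile` type 7); the IQR outlier fence is `k = 1.5`.
- Missing values: interior gaps linearly interpolated, edge gaps filled
  with the nearest finite value; the baseline mean is NA-aware.
- Common-axis interpolation clamps outside a series' native span
  (endpoint hold), matching plain 1-D interpolation behaviour.
- Constant series: amplitude 0, SD 0, CV defined as 0; entropy 0 with a
  degenerate-range warning; dominant frequency is an error (undefined).
- Exact-tie decoder slots are errors; exact-threshold binarization is 1
  (the ≥ rule).
- Exponential fits warn (`degenerate = TRUE`) when the response is
  constant or the rate pins at 0; non-convergence after bounded
  restarts is an error, not a silent fallback.
- dB floor −120 for zero-power spectrogram cells; reference power 1.

## Problem sizes in the test-suite and reproduction script

The synthetic-recovery checks run at sizes chosen to make the
statistical tolerances meaningful at desk scale: colored-noise slope
recovery at n = 2^15 over 50 seeds per exponent (each fitted slope
within ±0.3 of −β), exponential-decay recovery on a 10-point grid over
50 seeds (exact to 1e-6 relative when noiseless; within 3 fitted
standard errors at 2% noise), coherence floors with 31 averaged
segments, and a 100-message stimulus round trip. The
`scripts/acceptance.R` entry point recomputes the QFI quantities from
the published recording statistics (SDs 102.72/80.69/68.42 mV, dominant
frequency 0.063 Hz) with `qfi()` and `qfi_curve()` on the default
0.01–0.5 Hz grid.

## Known limitations

- Reproducing the published raw-data results (PSD slopes −3.84/−3.11/
  −3.24, MSC peaks 0.90/0.85, entropies 2.60–2.90 bits, the capacitance
  t = 9.18) requires the archived recordings; the package ships the
  loaders and estimators and validates them by synthetic recovery.
- The QFI proxy is a classical statistic; no quantum-state model is
  implied.
- Phase-specific coefficients of variation tied to unstated phase
  boundaries of the raw traces are not reproduced.
- Uncertainties quoted on descriptive metrics in the source tables come
  from an unstated resampling scheme; the package reports point
  estimates.
- The two long recordings are treated as independent series; no
  cross-epoch alignment rule is assumed beyond explicit
  `interpolate_common_axis`.
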