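---
title: "Multidomain features and SVM classification of heart sounds: methods"
author: "pcgclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidomain features and SVM classification of heart sounds: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgclass)
```

## The problem

A phonocardiogram (PCG) records the sounds of the beating heart from a
chest-wall sensor. Automatic screening asks two questions of each
recording: is the signal quality good enough to interpret, and does the
heart sound normal or abnormal (typically because of murmurs)? This
package implements a complete classification pipeline for single-channel
PCG recordings: preprocessing, four-state segmentation (S1, systole, S2,
diastole), extraction of 515 features from nine signal domains, RBF-kernel
support vector machines for quality and diagnosis, and the weighted
sensitivity/specificity scoring used by the PhysioNet/CinC 2016 challenge,
in which uncertain decisions are forgiven on poor-quality records only.

Because the challenge database is an external download, the package ships
a synthetic PCG generator that provides labeled recordings with exact
ground-truth state boundaries; every stage of the pipeline is developed
and tested against it.

## Preprocessing

Each recording passes through a fixed chain:

1. **High-pass at 10 Hz** (order-2 Butterworth) to remove baseline drift.
   The filter is applied forward-backward (`filtfilt`), so it is
   zero-phase: state boundaries are not shifted by filter delay.
2. **Spike removal.** The signal is cut into 500 ms windows and each
   window's maximum absolute amplitude (MAA) is found. While any window
   MAA exceeds 3x the median MAA, the offending spike is located and the
   signal is zeroed between the surrounding zero-crossings. The window
   length and threshold factor are configurable; the defaults follow the
   windowed-median despiking procedure in common use for heart sounds.
3. **Normalization** to zero mean and unit standard deviation. A constant
   signal is an error, not a silent zero.

Normalization happens once, before segmentation; all features are
computed from the normalized signal. (The amplitude, energy and spectrum
*ratio* features are scale-invariant by construction anyway, so this
choice only affects features with absolute units, i.e. the raw spectrum
magnitudes and cepstra.)

The working sampling rate is 2000 Hz: the energy features use bands up to
820 Hz, so the Nyquist frequency must exceed that; 2000 Hz is also the
convention of the challenge data. `read_wav()` resamples other rates with
a polyphase resampler.

## Segmentation

All 515 features depend only on the *segmentation interface* — an ordered
list of labeled state intervals — so the segmenter is pluggable:
ground-truth or externally produced annotations can be passed anywhere a
segmentation is accepted (`segment_pcg(rec, annotations = ...)`). The
built-in segmenter is deliberately simple, not a research-grade
duration-dependent HMM:

* the homomorphic envelope (exponential of a low-pass-filtered
  log-magnitude of the analytic signal) is computed and decimated to a
  50 Hz decision grid;
* heart rate is estimated from the envelope autocorrelation peak in the
  30–200 bpm band (no plausible peak is an error), and the systolic
  interval from the early autocorrelation peak;
* a duration-constrained Viterbi decoder walks the cyclic state order with
  Gaussian emissions on the envelope and truncated-Gaussian duration
  priors (S1 122±49 ms, S2 92±35 ms; systole and diastole derived from
  the estimated cycle). Ties break toward the earliest boundary via the
  fixed scan order.

On clean synthetic recordings the decoder recovers about 93–94% of state
labels sample-wise (the acceptance suite requires ≥ 90% over ten seeds).
It is not expected to match a trained HSMM on real, noisy data — that is
what the annotation-injection path is for.

## The nine feature domains (515 features)

| Domain | Count | Content |
|---|---|---|
| time intervals | 20 | mean/SD of RR, state intervals, per-beat ratios |
| per-state spectra | 308 | 77 grid magnitudes (30–790 Hz, 10 Hz steps) × 4 states |
| normalized amplitude | 12 | mean/SD of per-beat mean-absolute-amplitude ratios |
| energy | 47 | 27 band-energy ratios + 20 state-energy ratio statistics |
| record spectrum | 27 | per-band magnitude shares of the whole-record DFT |
| cepstrum | 65 | 13 coefficients × (record + 4 joined states) |
| cyclostationarity | 4 | mean/SD of degree-of-cyclostationarity and peak sharpness |
| higher-order statistics | 16 | mean/SD of per-state skewness and kurtosis |
| entropy | 16 | mean/SD of per-state SampEn and FuzzyMEn |

Decisions the definitions leave open, and how this package resolves them:

* **Per-state spectra.** Each state slice is windowed with a Gaussian
  window of SD = length/6, zero-padded to a power of two giving ≤ 10 Hz
  bin spacing, and the magnitude spectrum (normalized by slice length so
  cycles of different length average comparably) is read at the nearest
  bin to each grid frequency, then averaged over cycles.
* **Record-spectrum ratios.** "Whole band" is 10–820 Hz, the union of the
  27 energy bands; a DFT bin belongs to the half-open band [a, b), so
  shared band edges are unambiguous and the 27 ratios sum to exactly 1.
* **Cepstrum.** The real cepstrum is IDFT(log |DFT|). Zero magnitudes are
  floored at 1e-12 × max|P(k)| so the log never produces −Inf.
* **Cyclostationarity.** The cycle-frequency spectral density of each 3 s
  non-overlapping subsequence is estimated as the DFT magnitude of the
  demeaned squared Hilbert envelope (an envelope-spectrum estimator). The
  basic cycle frequency is the largest peak within 0.5–2.5 Hz
  (physiological heart rates); the normalizing integral runs over
  (0, 10 Hz] by the rectangle rule. Subsequence length, search band, and
  the 10 Hz ceiling are configurable.
* **Entropy.** SampEn uses m = 2, r = 0.2 × slice SD. FuzzyMEn combines a
  local term (templates centered by their own mean) and a global term
  (centered by the series mean) with membership exp(−d²/r). Slices are
  subsampled to ≤ 1000 Hz before the quadratic-cost entropy computations.
* **Moment conventions.** Skewness is Fisher's g1; kurtosis is non-excess
  (Gaussian → 3).
* **Missing values.** Anything that cannot be computed (fewer than two
  cycles for an SD, a zero-energy denominator state, a too-short slice)
  is `NA`, never silently zero; imputation is the model's job.
* The state-to-state energy ratio list follows the canonical 10-ratio
  table (which includes diastole/systole but not its reciprocal).

## Models and the uncertain rule

`pcg_svm()` fits a soft-margin SVM. The Gaussian RBF kernel
exp(−‖x−y‖²/(2σ²)) with σ = 14 is the default (σ = 14 is the grid-search
optimum reported for this feature set on the challenge database); the
non-squared exponential (Laplacian) form exp(−‖x−y‖/γ), which also
appears in this literature, and a linear kernel are options. C defaults
to 1. Columns are median-imputed and z-scored with training-split
statistics only — an RBF over raw heterogeneous units (seconds vs ratios
vs magnitudes) would be dominated by scale. Class-balanced penalty
weighting is available but off by default (the plain SVM mirrors the
reported behavior on the heavily unbalanced quality labels, where the
noisy class is found only about half the time).

The three-way output (normal / uncertain / abnormal) is produced by a
documented rule of this package, since only the scoring of "uncertain" is
fixed by the challenge: a record is uncertain iff the quality model
predicts noisy *and* the absolute diagnosis margin is below τ (default
0.3). τ = 0 disables the uncertain class; τ = ∞ sends every
predicted-noisy record to uncertain.

## Scoring, ranking, protocols

Scoring follows the challenge algebra exactly: 12 confusion cells over
reference categories (normal/abnormal × clean/noisy) and decisions
(normal/uncertain/abnormal), prevalence weights wa1 + wa2 = wn1 + wn2 = 1,
and weighted Se/Sp in which uncertain counts as correct only for noisy
records; overall = (Se + Sp)/2. Zero-denominator terms contribute 0 with
a warning. Weights default to the evaluated cohort's own reference labels
(full-cohort weights can be supplied explicitly).

Feature ranking uses Pearson correlation with the label (Spearman
optional), missing values pairwise-excluded, constant features ranked
last, ties broken by canonical order. Domain contributions are compared
lexicographically on top-10, then top-100/200/300 membership counts.

Evaluation protocols: repeated stratified random splits (sampling each
diagnosis class separately; a single-class training split is resampled
with a message), the memorization case (train fraction 1, test = train),
stratified k-fold cross-validation pooling decisions so each record is
tested exactly once, and per-domain runs. Per-repeat seeds are derived
from the master seed with an integer mixing function, so any repeat is
reproducible alone.

## The synthetic generator: what it does and does not emulate

`generate_recording()` renders quasi-periodic cycles with multiplicative
Gaussian period jitter (truncated at 3 SD, default 3%), S1/S2 as
Hanning-windowed two-tone bursts (60/110 Hz and 85/140 Hz) with per-beat
amplitude and phase variation, murmurs as Butterworth band-limited white
noise (default 150–600 Hz) confined to the systolic and/or diastolic
state at a configurable level relative to S1 RMS, a stationary low-pass
(< 100 Hz) background noise floor, and optional friction-like spikes.
Defaults: 2000 Hz, 10 s, 72 bpm, S1 122 ms, S2 92 ms, systole 20% of the
cycle, murmur −6 dB, background noise 30 dB SNR. The low-pass noise color
matters: ambient and sensor-contact noise in auscultation is dominated by
low-frequency rumble, and it gives the murmur class its higher systolic
entropy and high-band energy — the discrimination directions the feature
set exploits.

The generator makes no attempt at hemodynamic realism: no split S1/S2, no
pathology-specific murmur morphology (crescendo/decrescendo), no
respiration modulation, no sensor transfer function. Passing tests on
synthetic data therefore demonstrate that the pipeline measures what it
claims to measure (the oracles and partition identities) and that it
separates classes whose differences are the ones the features target —
not that real-database scores are reproduced. Reproducing published
database scores requires the external download and is out of scope for
the test suite.

The labeled-dataset conditions used by the acceptance checks are: 200
recordings (100 normal, 100 abnormal), 8 s each, heart rate uniform
60–100 bpm, strong murmurs (0 dB relative to S1, type sampled
systolic/diastolic/both at 0.5/0.3/0.2), 10% of recordings degraded to
poor quality (5 dB noise + spikes). Cross-validated challenge scores on
this cohort are computed with 10 folds and averaged over 5 fold seeds;
the repeated-split trend compares training fractions 0.1 and 0.9 with 10
repeats each. These sizes keep a full run in a couple of minutes on one
CPU while leaving the score criterion (overall ≥ 0.90) a real test of the
pipeline rather than of the generator.

## Numerical notes and limitations

* The 27 band-pass filters are 5th-order Butterworth IIR designs; at
  2000 Hz all 27 are stable, but the lowest band [10, 40] Hz is
  marginally damped, so band energies are reproducible but not bitwise
  invariant under arbitrary (non-power-of-two) rescaling of the input.
* `filtfilt` has edge transients of roughly one filter time constant at
  each end; the 10 Hz high-pass assertion in the tests therefore inspects
  the steady-state interior.
* SampEn is undefined when no template pair matches (B = 0) and returns
  `NA` rather than infinity; FuzzyMEn likewise guards degenerate
  similarity averages.
* The Viterbi decoder requires ≥ 2 s of signal and a detectable
  autocorrelation peak; recordings failing either raise errors that the
  higher-level table builders propagate per record.
* Quality labels of the synthetic generator are a threshold convention
  (noise SNR < 15 dB or any spikes ⇒ poor quality), not a learned notion
  of interpretability.
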