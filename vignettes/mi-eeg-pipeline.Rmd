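---
title: "Motor-imagery EEG features, significance screening and cross-validated classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-imagery EEG features, significance screening and cross-validated classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mieeg)
```

## The problem

In a motor-imagery brain-computer interface (BCI), a subject imagines a
movement (left hand, right hand, feet, tongue) and the system must decode
which one from multichannel EEG. The physiological signature is subtle:
imagining a movement attenuates band-limited oscillatory power — mostly in
the alpha (8-13 Hz) and beta (13-30 Hz) bands — over the corresponding
sensorimotor cortex (event-related desynchronization, ERD). Decoding
pipelines therefore summarize each trial segment by a feature vector,
discard features that carry no class information, and train a classifier on
the rest.

`mieeg` implements such a pipeline end to end for 22-channel, 3-second
segments sampled at 250 Hz:

1. **Feature extraction** — 62 features per channel, 1,364 per segment:
   - 24 time-domain descriptors (extrema, moments, integrated amplitude
     measures, waveform length, Hjorth parameters, quartiles,
     zero-crossing/slope-sign-change counts, ...);
   - 15 FFT subband features: energy, variance and entropy of the one-sided
     spectrum restricted to each of the five canonical EEG bands (delta
     0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-100 Hz);
   - 15 wavelet subband features: the same three statistics on pooled Haar
     wavelet-packet coefficients mapped to the same five bands;
   - 8 lagged Poincare descriptors: SD1, SD2, SD1*SD2 and SD1/SD2 at lags 1
     and 9.
2. **Significance screening** — one p-value per feature (independent pooled
   t-test for two classes, one-way ANOVA otherwise); keep features with
   p < 0.05.
3. **Evaluation** — repeated stratified 5-fold cross-validation over a grid
   of classifier families, including a from-scratch random-subspace
   regularized-discriminant ensemble.
4. **Synthetic ground truth** — a class-conditioned EEG generator that
   mimics ERD, so every stage is testable without external recordings.

## Feature definitions and numerical conventions

**Time domain.** Standard deviation and variance use the sample (N-1)
denominator. Kurtosis is the biased non-excess estimator (a Gaussian signal
gives about 3), skewness the biased estimator. The amplitude measures are
`ieeg = sum(|x|)`, `mav = ieeg/N`, `ssi = sum(x^2)`, `rms = sqrt(ssi/N)`,
waveform length `wl = sum(|diff(x)|)`, average amplitude change
`aac = wl/(N-1)`, and `dasdv = sqrt(sum(diff(x)^2)/(N-1))` (the standard
deviation of successive differences, the usual reading of "absolute
difference of standard deviation" in the EMG/EEG feature literature).
Continuous signals have no repeated values, so the mode is taken after
rounding to 2 decimals, ties broken toward the smallest value (both
configurable). Quartiles interpolate linearly between order statistics.
Zero crossings count strict sign products `x[i]*x[i+1] < 0` and slope-sign
changes strict products of consecutive differences; no amplitude threshold
is applied. Hjorth mobility and complexity use plain first differences —
they are ratios, so the sampling-interval factor cancels; a zero-variance
signal returns mobility = complexity = 0 rather than NaN.

**FFT subbands.** Bands are half-open intervals `[low, high)` on the
one-sided DFT grid (bin k at `k*fs/N` Hz), so adjacent bands never share a
bin; with `fs = 250`, `N = 750`, alpha holds bins 24-38 (M = 15). Band
energy is `sum(|Y_k|^2)`. Band variance is the sample variance of the
magnitudes `|Y_k|` (a variance of complex coefficients is otherwise not a
single real number). Band entropy is normalized Shannon entropy
`-(1/log M) sum(p log p)` of the in-band power shares, so it lies in [0, 1]
— 1 for a flat in-band spectrum, near 0 for a single line. It measures
spectral regularity, which fixes the conventional minus sign. No taper is
applied by default (a Hann option exists); energy at round-off level
relative to total power (the FFT of a constant) is reported as exactly
zero.

**Wavelet subbands.** The signal is decomposed with orthonormal Haar
filters into the full wavelet-packet tree of depth 7 (the `aij`/`dij`
notation of plain dyadic decompositions is available as a `dwt` config
mode, but the packet tree is the primary path). The 128 terminal nodes tile
[0, 125) Hz in 0.977 Hz steps once the natural (Paley) node order is
remapped to frequency order by the binary-reflected Gray code — without
this remap every band above level 1 would pool the wrong nodes. Each node
is assigned to the band containing its center frequency, with two boundary
rules: content centered below the lowest band edge folds down into delta
(so DC and slow drift are counted there), and nodes centered above 100 Hz
(the upper gamma edge) are discarded. Signals whose length is not a
multiple of 2^7 are zero-padded up to the next multiple; the padding
contributes only boundary-pair coefficients. Per band, the mapped nodes'
coefficients are pooled into one vector `c`; energy is `sum(c^2)`, entropy
is the (unnormalized) Shannon entropy of `c^2/sum(c^2)` with `0 log 0 = 0`
(the literal unnormalized form `sum(c^2 log c^2)` is available behind
`entropy_form = "raw"` for comparison), and variance is the sample variance
of `c`.

**Poincare descriptors.** The m-lagged Poincare plot scatters `x[i]`
against `x[i+m]` on the raw segment amplitudes. Rotating by 45 degrees
gives `xa = (x[i+m]-x[i])/sqrt(2)` and `xb = (x[i+m]+x[i])/sqrt(2)`; SD1
and SD2 are their sample standard deviations (minor/major ellipse axes,
short- vs long-term variability). The product and ratio complete the four
descriptors per lag; SD2 = 0 reports the ratio as 0 so feature matrices
stay finite. Lags 1 and 9 are the defaults.

## Screening and its caveat

The screen computes one p-value per column: Student's pooled-variance
t-test for two classes (a Welch flag exists), one-way fixed-effects ANOVA
for more. Selection is the strict rule `p < alpha` with `alpha = 0.05` and
no multiple-testing correction — the screen is a per-feature filter whose
false-positive rate is the nominal alpha, not a family-wise claim; an
optional Benjamini-Hochberg flag is provided as an extension. Degenerate
columns follow fixed conventions (both groups constant and equal: p = 1;
constant and different: p = 0), so the screen never crashes on a flat
feature.

By default screening is fit once on the full dataset before
cross-validation, replicating the screen-then-classify sequence this
pipeline evaluates. That leaks label information into the CV estimate when
effects are weak; `selection_timing = "per_fold"` re-fits the screen inside
every training fold and is the methodologically safer alternative. On the
strongly separable synthetic data the two give similar results; on real
data the per-fold mode should be preferred when the absolute accuracy
matters.

## Classifiers

The preset grid approximates the familiar classification-learner families:
trees (fine/medium/coarse via depth budgets), linear and quadratic
discriminants, Gaussian and kernel-density Naive Bayes, SVMs
(linear/quadratic/cubic and three Gaussian kernel scales `sqrt(p)/4`,
`sqrt(p)`, `4*sqrt(p)` at box constraint 1), six k-NN variants (k = 1, 10,
100; cosine and Minkowski-3 distances; inverse-squared-distance weighting),
binary logistic regression, and five 30-learner ensembles: AdaBoost (SAMME)
boosted trees, bagged trees, RUSBoosted trees (boosting with per-learner
random undersampling to the minority class), random-subspace k-NN, and the
random-subspace discriminant. These are stated approximations of named
presets, not bit-matched reproductions of any external tool.

The subspace discriminant — the ensemble of interest — draws 30 random
feature subsets of size `ceiling(p/2)`, fits a regularized linear
discriminant on each (pooled within-class covariance with diagonal loading
`S + 1e-3 * tr(S)/p * I`, so the fit exists even when features outnumber
samples), and averages class posteriors; ties break toward the lowest class
index. Singular quadratic discriminants fall back to a per-class diagonal
Gaussian with a warning flag rather than crashing, mirroring how a
full-feature-set fit can be infeasible for covariance-based models.

Distance- and margin-based families (k-NN, SVM, logistic, subspace k-NN)
are standardized with training-fold mean and standard deviation inside each
fold; trees and discriminants run on raw features. Cross-validation is
stratified (per-class fold counts differ by at most one), re-randomized
every repeat from a seed substream, and reports mean accuracy, macro
one-vs-rest sensitivity and specificity in percent (for two classes, the
first class is the positive one).

## The synthetic generator

Each channel of a synthetic segment is the sum of a 1/f^gamma background
(gamma = 1) and one band-limited random-phase oscillation per EEG band,
both built by FFT-masking white noise — filtered noise rather than
sinusoids, so within-band variance and entropy behave like real broadband
oscillations. The default amplitude profile (delta 2.0, theta 1.2, alpha
2.0, beta 0.8, gamma 0.4 relative units, background 1.0, all scaled by 10
to microvolt-like values) gives the low-frequency-dominant spectrum of
resting EEG. The class effect is ERD-like amplitude attenuation only: on a
class's affected channels the affected band's amplitude (alpha by default)
is scaled by `1 - effect_size`, with `effect_size = 0.8` by default. The
default class-to-channel map uses disjoint sensorimotor triplets of the
22-electrode montage (left hand -> FC4/C4/CP4 contralateral, right hand ->
FC3/C3/CP3, feet -> FCz/Cz/CPz midline, tongue -> C5/C6/P1). One root seed
drives a per-segment substream, so datasets are bit-reproducible under any
generation order, and the null generator is the identical process with the
effect forced to zero — labels are assigned but carry no information.

What the generator does *not* emulate: volume conduction and channel
correlation from a head model, eye-blink/EMG artifacts, phase or latency
effects, non-stationarity across a session, and between-subject
variability. Passing tests on this data therefore demonstrate that the
pipeline recovers band-power class structure and is statistically
calibrated under a true null — not that any particular accuracy carries
over to real recordings, where effects are far weaker than the
demonstration's `effect_size = 0.9`.

## Problem sizes and checks

The test suite and `scripts/acceptance.R` run two study-scale
demonstrations chosen to finish in minutes on one CPU: a null calibration
at 4 classes x 25 segments/class (the screen should select about 5% of the
1,364 features; a discriminant's CV accuracy should sit inside a
3-binomial-SD band around the 25% chance level) and a signal-recovery run
at 2 classes x 100 segments/class with `effect_size = 0.9` (the screen must
retain every injected alpha-energy feature on the affected channels and the
subspace-discriminant ensemble must exceed 90% accuracy). Cross-validation
uses 5 folds with 2 repeats in these demonstrations; the package default is
10 repeats. Structural counts are exact consequences of the architecture
and are asserted as such: 22 x 24 = 528 temporal, 22 x 15 = 330 FFT, 330
wavelet and 22 x 8 = 176 Poincare features (1,364 total), and the
9-subject, 6-run, 48-trial design enumerates 2,592 four-class and 1,296
two-class trials.

Numerical behavior is pinned by independent oracles in the tests: Poincare
SD1/SD2 against brute-force pair enumeration (1e-12), Hjorth parameters
against direct variance ratios (1e-12), F = t^2 for two groups (1e-10),
Haar packet and FFT Parseval identities (1e-6 relative), tone-at-node-center
localization for the packet frequency ordering, the exact Dirichlet
expectation of normalized spectral entropy under white noise, MASS::lda
agreement for the degenerate one-learner full-space ensemble, and
class::knn agreement for the Euclidean k-NN path.

## Known limitations

- The EDF reader/writer covers plain EDF (one sampling rate, no
  annotations); it exists so segments can be exchanged with standard tools,
  not as a general EDF library.
- Kernel Naive Bayes evaluates a per-feature KDE per test point and is slow
  in high dimensions; it is intended for screened feature sets.
- The screen tests each feature marginally; correlated informative features
  are all retained (no redundancy removal), and with no multiplicity
  correction the selected set under weak effects contains about
  `alpha * p` false positives by construction.
- Preset hyperparameters are approximations; absolute accuracies are not
  comparable against tools whose presets differ, which is why the package's
  checks are calibration and recovery properties rather than accuracy
  values.
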