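---
title: "Methods: PPG-based glucose estimation with criterion-fused polynomial smoothing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPG-based glucose estimation with criterion-fused polynomial smoothing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

glucofuse estimates blood glucose from wearable multi-wavelength
photoplethysmography (PPG). A PPG is the optical record of blood-volume
pulsation: a steady (DC) absorption level plus a pulsatile (AC) component,
both of which respond to the near-infrared absorption of glucose, and whose
beat-to-beat timing carries heart rate variability (HRV) — itself linked to
glycemia through autonomic regulation. The pipeline is: denoise each
channel, extract a 103-dimensional feature vector per measurement,
normalise, smooth the training features (or the reference glucose) with
cubic polynomials fitted under one of three error criteria, select features
with a random forest, regress, and optionally fuse the three criteria with
a validation-driven region rule. Every model is trained and evaluated
within one subject ("individual modelling") because optical response varies
strongly across skin and tissue.

## Signal model and the synthetic generator

The real measurement campaign this pipeline targets (eight channels per
acquisition: four fast 880 nm channels at 1000 Hz for HRV, two 1450 nm and
two 1650 nm channels at 50 Hz for absorption) is not publicly archived, so
the package ships a generator that emulates the statistical structure the
pipeline relies on:

* **Waveform.** Each beat contributes a two-Gaussian pulse (systolic peak,
  plus a dicrotic bump at 0.4 of the beat period), scaled by an AC
  amplitude; a DC level, a slow sinusoidal baseline drift (0.03 Hz) and
  white noise complete the channel. The absorption channels carry a
  glucose-coupled DC level (affine, rising with glucose) while the AC
  amplitude falls with glucose, saturating at a positive floor. The 880 nm
  channels are generated AC-coupled (zero DC), as fast HRV-oriented
  front-ends high-pass their output; this also means the "keep the first
  singular-spectrum component" denoising step (below) retains the
  pulsatile waveform on those channels rather than a DC plateau.
* **Beat timing.** Intervals average 800 ms, modulated by sinusoids at the
  LF (0.1 Hz) and HF (0.25 Hz) band centres plus white jitter (10 ms SD).
  Hyperglycemia shrinks the HF modulation depth and shortens the mean
  interval slightly, mirroring reduced autonomic regulation, so the HRV
  and heart-rate feature blocks genuinely carry glucose information.
* **Protocol.** Twelve simulated days with three daily meal slots
  (7.5 h, 12.5 h, 18.5 h after midnight): a low-glucose ketogenic phase
  (days 1–4, mean 4.4 mmol/L), a normal phase (days 5–8, mean 6.0), and a
  high phase with post-meal spikes (days 9–12, mean 8.2 + 2.2 spike), an
  AR(1) wander on top, clamped into the configured glucose range. Blood
  pressures are drawn from N(118, 8) / N(76, 6) mmHg.
* **Determinism.** All randomness derives from one root seed through a
  fixed per-subject / per-measurement hash, so identical configurations
  reproduce byte-identical datasets.

What the generator does **not** emulate: optical tissue physics
(Lambert–Beer), sensor contact artefacts, motion, cross-subject optical
diversity, or any calibrated forward model from glucose to waveform
morphology — no such model is published for this device class. Passing
tests on synthetic data therefore demonstrate the pipeline's mechanics and
self-consistency, not clinical accuracy.

## SSA bit-plane denoising

Each channel is decomposed by singular spectrum analysis with embedding
window L = 32 (yielding exactly 32 additive components, ordered by
singular value). Each component is represented in 13-bit sign-magnitude
fixed point at a full scale equal to its own peak magnitude; the number of
"noise bits" is `floor(log2(sigma/q))` where `q` is the quantisation step
and `sigma` the component's noise level; those low-order bit planes are
zeroed; the components are summed; SSA runs a second time and the
component with the largest singular value is the denoised PPG.

Numerical choices worth stating:

* The noise level is estimated from **second differences**,
  `median(|x[t+1] - 2x[t] + x[t-1]|) / (0.6745 sqrt(6))`. A
  first-difference estimator is biased upward on any component with a
  locally linear trend (a ramp's differences *are* its slope), which is
  exactly what smooth SSA components look like; the second difference
  annihilates linear trends and stays unbiased for white noise.
* Quantisation is symmetric round-to-nearest with 1 sign + 12 magnitude
  bits; the full-scale sample saturates at the largest magnitude code, so
  the worst-case round-trip error at b zeroed bits is
  `(2^b + 1) q / 2 <= 2 FS / 2^12` for b = 1.
* With `2L > N` the decomposition raises an error rather than silently
  shrinking the window, keeping "32 components" an invariant.
* Retaining only the first component after the second pass follows the
  published procedure. On a short window relative to the beat period
  (32 ms at 1000 Hz) the first component acts as a local smoother and
  preserves the pulse train; on the 50 Hz absorption channels it
  converges to the DC level plus the dominant oscillation, which is what
  the absorption features need. A grouping that keeps several components
  would preserve more AC detail but is deliberately out of scope.

## The 103 features

Per measurement: 1 meal-timing feature (hours since the previous meal,
wrapping across midnight); 2 blood pressures; 8 absorption features (mean
and sample variance of each denoised 1450/1650 nm channel); 52 HRV
features (13 per 880 nm channel); 40 heart-rate statistics (10 per 880 nm
channel). Peaks are detected on the denoised signal as local maxima above
mean + 0.3 SD of a centred 5 s window with 0.333 s minimum separation;
peak-to-peak intervals outside 333–1500 ms are discarded. Time-domain HRV
uses sample (n−1) deviations, NN50 counts successive differences strictly
above 50 ms. Frequency-domain HRV cubic-spline-resamples the tachogram to
4 Hz, removes the mean, and integrates a Welch periodogram (Hamming
window, segments of `min(256, N)` with 50% overlap) over VLF [0, 0.04),
LF [0.04, 0.15) and HF [0.15, 0.4) Hz; LF/HF is capped at 1e6 when HF is
zero so downstream fits stay finite; normalised powers use the LF+HF
denominator. Heart-rate statistics include a histogram mode on 1-bpm bins
(ties to the lowest bin), non-excess kurtosis, and the unscaled median
absolute deviation, with the zero-variance convention skew = kurt = 0.

## Normalisation and polynomial smoothing

Every feature column is scaled to unit energy on the training block
(`g = 1/sqrt(sum(x^2))`); test columns reuse the training gains and are
never smoothed (smoothing requires the reference glucose, which is the
quantity being predicted at test time).

Smoothing fits cubic polynomials after sorting rows by ascending reference
glucose (stable, ties by original index, one shared permutation):

* **Feature smoothing** regresses each feature column on glucose and
  replaces the column by its fitted values.
* **Reference smoothing** regresses glucose on each feature column and
  averages the per-feature fitted vectors. The per-feature fits all use
  the *original* glucose vector (parallel averaging); chaining the fits
  feature-by-feature would make the result depend on the arbitrary feature
  order.

Three criteria define the fit: least squares (closed-form normal
equations), least absolute deviations, and minimax. The latter two are
linear programs — one slack variable per point bounding the absolute
residual for L1, a single scalar slack for L∞ — solved by the simplex
method with free-sign coefficients split into positive/negative parts.
Fits run on an abscissa rescaled to [−1, 1] (unit-energy features are
tiny, and cubing them underflows the conditioning of the Vandermonde
matrix); coefficients are mapped back exactly through the binomial
expansion. Order 3 is the default and the package's tested configuration;
the LPs are exact, and their optima are cross-checked in the test suite
against solver-free combinatorial oracles (an optimal L1 cubic
interpolates four points; a minimax cubic on a sorted abscissa
equioscillates on five points with alternating residual signs).

One practical caveat the tests document: a cubic has enough leverage that
an extreme outlier at the *end* of the abscissa is partially chased even
by the L1 criterion; robustness to interior outliers is what the sparse
criterion actually buys.

## Fusion

The training block splits 2/3 new-train, 1/3 validation (after the 75/25
train/test split this is 50% / 25% / 25% of all data). For each criterion
the new-train features are smoothed under it, the top 25 features by
random-forest impurity importance are selected, a 100-tree random forest
is trained, and validation absolute errors are recorded. Errors are sorted
by ascending validation glucose; each point's winner is the criterion with
the smallest error (ties resolved L1 > L2 > L∞, configurable). The sorted
axis is then partitioned: walking the winners, once at least
`min_region_points = 3` points have accumulated since the last reset, a
region closes when a criterion's running win fraction exceeds
ε = 0.6; the boundary is the midpoint to the next glucose value, the
region takes the maximal-fraction criterion, counts reset; tail points
form a final region by plurality. At test time the three forests each
produce an estimate; their mean only *locates* the region, and the output
is the estimate of that region's criterion (locators outside all
boundaries clamp to the outer regions).

Two semantics here were genuinely open. The accumulation rule as published
fires at the first point (any fraction is 1.0 after one observation);
`min_region_points` is the smallest change that makes it non-degenerate,
and it is configurable. Second, a single dominant winner necessarily
closes a region every `min_region_points` points under the literal rule;
since all those regions carry the same criterion the partition is
*equivalent* to one region — the package keeps the literal walk and the
tests assert the equivalent observable behaviour (every region carries the
dominant method and the fused prediction equals that model's output
exactly).

## Evaluation

Pearson R, MAE with the sample SD of absolute errors, RMSE, and MARD
(mean |est − ref| / ref, the standard accuracy figure for glucose
monitors), plus Clarke error grid zoning. The grid is defined in mg/dL;
mmol/L inputs are converted with 18.018 mg/dL per mmol/L. Zones follow the
original 1987 inequalities (A within 20% of reference or both below
70 mg/dL; E for opposite-extreme misreads; C and D the overcorrection and
failure-to-detect wedges; B the remainder), evaluated in the cascade
A, E, C, D, B.

## Problem sizes and what the checks show

The package's own verification runs at desk scale: cohorts of 1–2
synthetic subjects with 12–24 measurements of 35 s per channel in the test
suite, a 2 × 24 cohort in the reproduction script, 100 random instances
for the optimiser cross-checks, and 50 seeded trials per criterion for the
smoothing-recovery rate. The published study this pipeline re-implements
reports headline accuracy (MARD ≈ 0.093, zone-A ≈ 94%) on an eight-subject
physical dataset available only on request; those numbers characterise
that dataset and are not reproducible from synthetic data, so the
package's reproduction script reports the synthetic-cohort metrics it
actually computes and makes no claim of matching the physical-device
figures.

A known limitation worth stating plainly: on synthetic data whose raw
features are information-rich and whose test features share the training
noise distribution, the no-smoothing baseline approximates the
Bayes-optimal regression on the noisy features, and training on smoothed
features cannot beat it in expectation. The fusion machinery is therefore
validated here through its exact contractual behaviour (region
partitioning, winner selection, dominance collapse, split fractions) and
through the smoothing-recovery property (smoothed columns land closer to
the noiseless truth), not through a claimed accuracy gain over the raw
baseline — the published gain lives in unreliability structure of real
optical features that the generator does not pretend to reproduce.
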