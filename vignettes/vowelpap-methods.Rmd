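---
title: "Vowel acoustics and upper-airway diameter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vowel acoustics and upper-airway diameter: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vowelpap)
```

## The scientific problem

Obstructive sleep apnea (OSA) is characterized by repetitive collapse of
the upper airway during sleep. During wakefulness, vowel articulation is a
controlled maneuver that modulates the same airway: frontal vowels (/i/
as in "see", /u/) pull the tongue forward and widen the airway, back
vowels (/a/ as in "sah", /e/, /o/) narrow it. Submandibular ultrasound
can quantify this as the parasagittal anterior–posterior (PAP) diameter
in mm, and the airway configuration simultaneously shapes the vowel's
acoustics. `vowelpap` provides the full measurement-and-analysis chain:
a synthetic-cohort generator that emulates the study population, the
106-feature acoustic front end, the group statistics, and a stacked
machine-learning estimator of PAP diameter from acoustics alone.

Individuals are labelled by the NoSAS score — 4 points for neck
circumference ≥ 40 cm, 3 for 25 ≤ BMI < 30 or 5 for BMI ≥ 30 kg/m²,
2 for snoring, 4 for age ≥ 55, 2 for male sex; range 0–17, high risk at
≥ 8. All band edges are inclusive on the printed boundaries and BMI is
rounded to one decimal before banding (clinical convention).

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream stage is validated.

**What it emulates.** Two groups (18 controls, 13 high-risk) with
demographic Gaussians per group; rejection sampling enforces
NoSAS-consistency (a sampled "control" must actually score < 8). For each
participant and each of the five vowels it draws a PAP diameter, a pitch
and a second formant from per-(group, vowel) Gaussians; the /i/ and /a/
cells use the published group statistics verbatim, the unpublished
/u/, /e/, /o/ cells interpolate between them preserving the
frontal-wide / back-narrow ordering, and F1/F3 come from standard adult
vowel tables. Waveforms are synthesized with a Rosenberg-type glottal
pulse train (open quotient ~0.6, ≤ 1% period jitter), differentiated as
a lip-radiation approximation, filtered through three impulse-invariant
second-order resonators at (F1, F2, F3) with bandwidths (80, 120, 160)
Hz, plus Gaussian noise at 30 dB SNR; peak amplitude is normalized to
0.5. Durations are uniform on 0.6–1.0 s, the hardware sampling rate is
15,300 Hz.

**Latent structure.** Each participant carries an airway-openness latent
`z` and a voice latent `w`, both standard normal. PAP loads on `z` with
loading 0.9 across vowels (giving realistic within-person correlation of
See and Sah diameters); F2 loads on `z` with the `coupling` parameter
(default 0.7), and the glottal open quotient shifts mildly with
`coupling * z` (spectral balance). Pitch loads on `w` (0.95). Setting
`coupling = 0` severs the acoustics–PAP link, which the tests use as a
negative control. The default coupling was chosen once so the end-to-end
stacked estimator reaches a correlation materially above zero (≈ 0.7–0.8)
without being tuned to any published performance figure.

**What it does not emulate.** Room acoustics, microphone response,
loudness variation, dysphonia, inter-vowel coarticulation, or the
possibility that group differences in real speech are driven by factors
other than airway geometry. Passing recovery tests on this generator
therefore demonstrates that the estimators are unbiased and the pipeline
is leak-free under the modelled signal structure — not that the published
real-data effect sizes are correct.

**Distributional fidelity notes.** (1) The truncated-at-18 age Gaussian
is mean-corrected (the pre-truncation mean is solved numerically so the
generated population mean equals the configured one); the NoSAS rejection
step still shifts the control age marginal by roughly −0.3 years, which
is why the recovery test for demographics uses a ±1-year band rather than
a pure sampling standard error. (2) PAP truncation at zero uses
resampling, not clipping, preserving the mean to well under the sampling
error at the published means and SDs. (3) With the published per-vowel
SDs, no within-person correlation ≤ 1 reproduces the published See−Sah
delta SDs exactly (it would require a correlation above 1); the default
loading of 0.9 gives delta SDs of ≈ 4.3 mm (control) and ≈ 5.8 mm (OSA),
slightly above the published 3.9 / 5.3. Delta means are unaffected.

## Preprocessing

Segments labelled in a PRAAT TextGrid tier (`"vowel"`, labels
i/u/a/e/o) are sliced half-open, resampled to 10 kHz by polyphase
rational resampling (15,300 → 10,000 is 100/153), then band-pass filtered
100–3000 Hz with a 5th-order Butterworth applied forward–backward. Zero
phase preserves segment-internal timing for framing; the effective
magnitude response is the squared single-pass response, which is
acceptable because only magnitudes are used downstream. Segments shorter
than 0.2 s are dropped with a warning (20 ms framing needs roughly ten
frames for stable statistics) rather than zero-padded.

## The 106-feature inventory

pitch mean + SD (2); F1–F3 (3); band power, relative power and spectral
centroid in 10 bands — 100–3000 Hz, the six disjoint 500 Hz-wide
sub-bands, and 100–1000 / 1000–2000 / 2000–3000 Hz — (30); MFCC mean +
SD for 13 coefficients (26); chroma mean + SD for 12 pitch classes (24);
spectral contrast mean + SD in 7 octave-style bands (14); roll-off
mean + SD (2); zero-crossing rate mean + SD (2); spectral skewness,
kurtosis and entropy (3). This inventory covers every feature family the
pipeline names and sums exactly to 106; the order is fixed and shipped as
a manifest file.

Numerical choices worth knowing:

* **Pitch** — RAPT-style normalized cross-correlation over lags for
  60–400 Hz on 40 ms frames (10 ms hop), candidate peaks with parabolic
  lag interpolation, dynamic-programming path selection with a 0.4 cost
  per octave jump and a small short-lag preference (0.05 · log2 lag
  ratio) to resist period doubling; voicing threshold NCCF ≥ 0.3 (the
  usual default); unvoiced frames are excluded, and a fully unvoiced
  segment yields a missing sentinel.
* **Formants** — autocorrelation LPC of order 8 on pre-emphasized
  (0.97) 20 ms Hamming frames; polynomial roots with 90 < f < 4000 Hz
  and bandwidth < 600 Hz are candidates; the lowest three per frame,
  median-aggregated over frames. The common 400 Hz bandwidth cutoff was
  measured to drop the F2 pole in ~40% of frames on low-pitched voices
  (LPC-8 inflates pole bandwidths when harmonics sample the envelope
  sparsely), so the package default is 600 Hz; the parameter is exposed.
  For /u/ and /o/, whose F1 and F2 sit ~500 Hz apart, order-8 LPC merges
  the two poles in a share of segments and the estimator honestly
  returns the missing sentinel — the same low-formant inaccuracy known
  for real speech. Sentinels propagate to the feature table and are
  median-imputed (training folds only) inside the estimator.
* **Welch PSD** — 20 ms Hamming windows zero-padded to 512 FFT points,
  90% overlap, one-sided density; Parseval holds within 5%. "Band power"
  is the integrated density over in-band bins (reported in dB re digital
  full scale, as recordings are uncalibrated): on a discrete grid this is
  the only reading under which the six disjoint sub-band relative powers
  sum to exactly 1, which the package treats as an invariant.
* **MFCC** — 26 triangular HTK-style mel filters from 0 Hz to Nyquist on
  the 512-point spectrum, natural log with a 1e-10 floor, orthonormal
  DCT-II, 13 coefficients. Amplitude scaling moves only coefficient 0.
  The test suite cross-checks against an independent numpy
  implementation with matched settings (1% tolerance).
* **Chroma / contrast / roll-off / ZCR** — 20 ms frames, 10 ms hop;
  chroma is the per-frame energy fraction over pitch classes of bins in
  100–5000 Hz; contrast is the top-decile minus bottom-decile bin level
  (dB) in 7 octave-style bands with edges 0, 100, 200, 400, 800, 1600,
  3200, 5000 Hz; roll-off is the 85%-energy frequency. Spectral
  skewness/kurtosis/entropy (nats) treat the normalized 100–3000 Hz PSD
  as a probability distribution over frequency.

## Statistics

Test selection is gated by Shapiro–Wilk at α = 0.05 (on each sample;
for paired data on the differences): t-tests when normal, otherwise
Wilcoxon signed-rank (Pratt zero-difference handling, so degenerate
all-zero fixtures give p = 1 deterministically) or Mann–Whitney U. The
unpaired parametric branch is Welch's t. The See→Sah group-difference
question uses a mixed two-way repeated-measures ANOVA (group between,
vowel within, subject error strata); with a two-level within factor its
interaction F equals the squared two-sample t on per-subject deltas,
which the tests exploit as an algebraic cross-check. Feature–PAP
correlations are Pearson or Spearman by the same gate. No
multiple-testing correction is applied — the heatmap CSV carries raw
p-values, matching the analysis being reproduced; users comparing many
features should apply their own correction.

All tests hold their nominal type-I rate within [0.03, 0.07] at
α = 0.05 over 1,000 null simulations in the test suite.

## The stacked estimator

Six-fold cross-validation (`by_observation` mirrors the published
125-train / 25-test arithmetic at n = 150; `by_participant` is offered as
the leakage-safe alternative since vowels of one speaker are otherwise
split across folds). Per fold, features are median-imputed and
standardized with training-fold statistics only, and standardized values
are clipped at ±6 SD — features nearly constant in a training fold
(zero-heavy chroma bins, sentinel-imputed formants) otherwise produce
extreme test-fold values that destabilize the linear and neural models.

Step-1 models, hyperparameters chosen once as standard small-data
defaults and documented here:

* linear regression via truncated-SVD least squares, keeping singular
  values above 3% of the largest. With 106 correlated features and ~125
  training rows, plain least squares near-interpolates (the feature set
  even contains exact dependencies: relative powers and chroma fractions
  each sum to one) and its out-of-fold predictions explode; spectral
  truncation is the package's conditioning choice and retains roughly
  two thirds of the spectrum on cohort-sized data;
* random forest, 500 trees, unlimited depth;
* a 64–32 rectified two-hidden-layer network, full-batch Adam
  (lr 0.005), up to 500 epochs with early stopping (patience 40) on a
  10% inner split;
* a 1-D convolutional network over the ordered 106-vector: two blocks
  (16 then 32 channels, kernel 5, max-pool 2) and a 32-unit dense head,
  Adam lr 0.002, up to 500 epochs, patience 60.

Step 2 is a random forest on the four out-of-fold prediction columns,
itself trained per fold on the other folds' out-of-fold predictions, so
no prediction ever sees its own target. Metrics are pooled out-of-fold
RMSE (mm) and Pearson r, plus per-fold mean ± SD. Determinism: linear
and forest models are exactly reproducible under a fixed seed; the
neural models additionally require single-threaded numerics.

## Problem sizes used in validation

Stochastic recovery checks use 20 replicate cohorts (pooled n = 360
control-vowel or 260 OSA-vowel measurements) and recover the configured
PAP means, See−Sah deltas, and — through the full synthesis →
preprocessing → estimation chain — the OSA /i/ pitch and F2 means within
two standard errors (F2 with an 8% systematic-bias allowance for order-8
LPC; measured bias is ~1%). Formant/pitch recovery is profiled on 200
vowels spanning the generator's ranges (median relative error budget: 5%
pitch, 8% formants). The label-permutation leakage check runs the full
stack 20 times with reduced capacity (80 trees, 50/30 neural epochs) —
the leakage property does not depend on capacity — and requires the mean
pooled r over permutations (and the mean |r|) to lie inside (−0.2, 0.2);
single permutation runs carry ~0.1 sampling noise at n = 155. The
repeated-measures interaction power check uses 60 replicate cohorts.

## Known limitations

* The generator's vowels are stationary; no diphthongization, loudness
  drift or breathiness beyond stationary noise.
* /u/ and /o/ formant sentinels (close F1–F2) mean those vowels
  contribute imputed formants to the estimator, as with real low vowels
  under order-8 LPC.
* The published per-vowel SDs and delta SDs cannot be matched
  simultaneously by any within-person correlation; means are exact,
  delta SDs are mildly inflated.
* Real-data headline performance (RMSE/r of the stack on the study's own
  recordings) is intentionally out of scope: it depends on unreleased
  audio and undisclosed hyperparameters.
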