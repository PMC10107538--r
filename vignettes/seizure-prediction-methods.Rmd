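---
title: "Methods: early EEG-based seizure prediction in neonatal HIE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early EEG-based seizure prediction in neonatal HIE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neoseize)
```

## The problem

Roughly a third of neonates with hypoxic-ischemic encephalopathy (HIE)
develop electrographic seizures, typically beyond 12 hours of age, while
the therapeutic window for neuroprotective decisions (e.g. starting
hypothermia) closes at about 6 hours.  The question this package
operationalises is whether the *early* EEG background — a 1-hour epoch
recorded before 12 hours of age and at least 1 hour before any seizure —
combined with early clinical observations, can predict which infants will
later seize.  Predictions are per-infant probabilities; performance is
summarised by the Matthews correlation coefficient (MCC), which is robust
to the ~1:2 class imbalance, alongside AUC, sensitivity, specificity, PPV
and NPV at the probability threshold where sensitivity equals
specificity.

## Pipeline

1. **Epoch selection** (`select_epoch`): the earliest 1-h window whose end
   falls before 12 h of age and at least 1 h before the first annotated
   seizure, with at least `min_usable` (default 0.5) of its samples
   outside annotated artifact intervals.  Candidate windows slide in 1-min
   steps.  Artifact handling (`mask_artifacts`) flags samples; every
   short-time estimator drops whole analysis windows that overlap the
   mask, and the frequency-domain filters zero masked samples first so
   high-amplitude transients cannot leak into clean segments.
2. **Quantitative background features** (`extract_features`), computed
   identically for the 8-channel montage and the 2-channel bipolar aEEG
   montage (F3-C3, F4-C4):
   absolute and relative band powers, spectral flatness, spectral
   difference, spectral edge frequency (95%), range-EEG margins and
   asymmetry, interburst-interval (IBI) statistics, amplitude skewness and
   kurtosis per band, Higuchi fractal dimension, brain symmetry index and
   magnitude-squared coherence.  A second, IBI-weighted copy of all
   non-IBI features (multiplied by the IBI fraction) is appended, plus two
   adjusting covariates: anti-seizure medication before the epoch and
   hypothermia at the epoch.
3. **Models** (`nested_loocv`, `run_prediction`): random forest (100
   trees, depth grid 1-4) for clinical and qualitative-EEG features;
   gradient boosting (40 iterations, learning rate 0.1, depth grid 2-6)
   for quantitative features.  The outer loop is leave-one-subject-out;
   depth is chosen per outer fold by stratified 10-fold cross-validation
   repeated 5 times, scored by mean out-of-fold MCC at threshold 0.5,
   ties to the shallower tree.  Mean imputation of missing predictors is
   fit inside each outer training set.  Combined models fuse the two
   single-model out-of-fold probabilities by the inverse-logit of the
   mean logit (`fuse`); feature matrices are never concatenated.
4. **Evaluation** (`metric_report`, `williams_test`, `cohens_kappa`):
   equal-sensitivity/specificity operating point, MCC and AUC with
   stratified subject-level percentile-bootstrap 95% CIs (2000 resamples,
   threshold re-fixed per resample), Hotelling-Williams t (df = n - 3)
   for comparing two models' dependent MCCs, Cohen's kappa for model
   agreement.

## Key parameter choices the source left open

* **Band scheme.** The methods text defines delta 1-4, theta 4-7, alpha
  7-13, beta 13-30 Hz while a table footnote uses 0.5-3 / 4-7 / 8-12 /
  13-30 Hz.  The package default follows the methods text;
  `band_scheme("narrow")` selects the footnote convention.  Band
  membership of a frequency bin f in (lo, hi) is `lo < f <= hi`.
* **Welch settings.** 2-s Hamming windows, 50% overlap (0.5 Hz
  resolution at 250/256 Hz); unstated in the source, standard for this
  feature set.
* **Spectral difference** has no published formula; here it is the median
  over consecutive short-time spectra of the mean absolute PSD change
  within the band, normalised by total 0.5-30 Hz power.
* **IBI weighting**: features are multiplied by the IBI *fraction*
  (percentage/100); the source is ambiguous between fraction and percent,
  and tree models are scale-invariant so only the reported feature scale
  is affected.
* **Amplitude skewness/kurtosis** are computed on the signed
  band-filtered signal (non-excess kurtosis, Gaussian = 3).  One clause
  of the internal feature description suggested skewness of |x|, but the
  worked examples and the magnitude of the published group medians are
  only consistent with the signed convention, which is used throughout.
* **Higuchi FD** uses k_max = 6 on 2-s windows of the 1-30 Hz signal
  *resampled to 64 Hz*, median-pooled.  At the native rate the band-limited
  signal is ~4x oversampled and all FD estimates collapse toward 1; at
  64 Hz the estimator recovers the literature anchors (white noise
  FD ~ 2, smooth curves ~ 1) and the published neonatal range 1.4-1.7.
* **IBI detector.** The cited preterm detector's internals are not
  public; the package uses a 0.5-s moving-RMS envelope of the 0.5-30 Hz
  signal, the across-channel maximum (an AND rule: every channel must be
  suppressed), an Otsu split of the log-envelope into its two amplitude
  modes (falling back to an absolute 5 uV RMS ceiling when the envelope
  is unimodal), 0.5-s gap hysteresis, and a 6-s minimum duration.
  Acceptance is via constructed-signal oracles, not the original
  detector.
* **Learner internals.**  No tree-ensemble package is assumed; both
  learners are implemented in compiled code with quantile-binned
  histogram splits (16 bins, fit on each outer training fold), the
  discretisation modern boosting libraries use.  Gradient boosting is
  logistic-loss with Newton leaf values clipped to +-4; the random
  forest uses bootstrap resampling, per-node `sqrt(p)` feature
  subsampling, Gini splits and probability averaging.  Ordered-boosting
  variants are not reproduced.
* **Inner-CV selection metric** is MCC (the study's primary metric) on
  stratified folds; both details are unstated in the source.  Fusion
  weights are equal.

## The synthetic cohort: a stated world

No recordings are deposited, so every end-to-end claim is exercised on a
generator (`generate_cohort`) whose class-conditional structure is
calibrated once, mechanically, from the published group tables:

* **Prevalence** 53/162 = 0.327.
* **EEG background**: a two-state burst/interburst log-normal renewal
  process shared across channels modulates band-limited (0.5-30 Hz)
  1/f-coloured noise.  Per class: burst/suppression RMS amplitudes chosen
  so the group-median delta power and range-EEG median land near the
  published medians (non-seizure ~10/4 uV giving delta ~30 uV^2;
  seizure ~6.5/2.8 uV giving delta ~4-5 uV^2 at 90% suppression); burst
  and IBI median durations (45/3 s vs 2.5/20 s) reproduce the near-zero
  vs ~90% IBI percentages; the 1/f exponent (2.1 vs 1.7) is derived from
  the fractal-dimension medians via FD ~ (5 - slope)/2; inter-hemispheric
  coupling (0.23/0.26) from the coherence medians via msc ~ coupling^2;
  the per-subject log-gain spread of the right hemisphere (0.30/0.35)
  from the BSI medians.  Per-subject jitter log-SDs come from the printed
  IQR ratios (sdlog = log(q3/q1)/1.349).
* **Clinical table**: truncated normals for continuous fields, Bernoulli
  or categorical for discrete, binomial(10, p) for the ordinal Apgar
  scores, with class-conditional parameters read from the published
  by-group summaries, and missing-completely-at-random cells at each
  field's observed missingness (3% for Apgar 1/5 up to 37% for lactate).
* **Qualitative flags** derive deterministically from each subject's own
  generator parameters (e.g. discontinuity when the subject's median IBI
  exceeds 6 s; low voltage at <= 25 uV peak-to-peak), except sleep-wake
  cycling, which has no generator analogue and is an explicit
  class-conditional Bernoulli.
* **Seizure annotations** are placed after the analysis epoch plus the
  1-h guard (onset log-normal, median 14.4 h), with event counts,
  durations and the seizure period drawn from the published
  seizure-characteristics table.

What a green test does establish: the full pipeline — EDF I/O, epoch
selection, masking, all estimators, nested CV, fusion, metrics — runs
end-to-end and separates the two programmed classes at MCC >= 0.5.  What
it does not establish: performance on real neonatal EEG.  The generator
contains no spindles, sharp waves, seizure waveforms, state transitions
or realistic artifact morphology, and its class separation is an
emulation of published summaries, not patient data.  The published
cohort-level numbers are covered only by the confusion-matrix
reconstruction targets, which are exact.

## Numerical and degenerate-input conventions

Zero or constant signals flag spectral flatness, SEF, FD, moments and
rEEG asymmetry as `NA` ("undefined"), and these are mean-imputed at
modelling time exactly like missing clinical values.  MCC returns 0 on
any zero marginal.  A degenerate threshold scan (all probabilities equal)
warns and returns 0.5.  Cohen's kappa of two identical constant raters is
1.  All intervals are half-open `[start, end)`; time is seconds from
record start internally and hours after birth at interfaces.

## Compute scaling in tests

The nested scheme at the published scale (n = 162-200, 1-h epochs,
multi-seed medians) costs tens of CPU-minutes.  The test suite and the
acceptance script run the identical code path on smaller instances
(n = 60 cohorts, 600-s epochs, 3 seeds, 5 permutation repeats), sized
from timing measurements *before* the criteria were evaluated; criterion
thresholds and tolerances are never adjusted.  The leakage audit uses the
`newdata` hook of `nested_loocv`: corrupting the held-out representation
of one subject must leave every other out-of-fold probability
bit-identical (corrupting the training copy would legitimately change
other folds' models, so that is not the audited path).

## Known limitations

* The EDF layer implements the continuous-recording subset of EDF/EDF+
  (equal per-signal rates, 1-s records, microvolt dimensions).
* The IBI detector is a calibrated stand-in for the cited preterm
  algorithm, not a reimplementation.
* Williams' test compares MCCs as if they were Pearson correlations of
  predictions with labels (they are, for binary predictions at a fixed
  threshold, phi coefficients), matching the study's usage; the
  inter-model correlation r12 must be supplied by the caller.
* Bootstrap CIs are percentile intervals; the study did not state its CI
  construction.
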