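Package: neoseize
Title: Early EEG and Clinical Prediction of Seizures in Neonatal
    Hypoxic-Ischemic Encephalopathy
Version: 0.1.0
Authors@R:
    person("NeoSeize", "Developers", email = "neoseize@example.org",
           role = c("aut", "cre"))
Description: Quantitative-EEG background analysis and machine-learning
    seizure prediction for neonates with hypoxic-ischemic encephalopathy.
    Reads multichannel EEG in European Data Format (EDF), selects the
    earliest artifact-masked one-hour epoch recorded before 12 hours of age
    and at least one hour before electrographic seizure onset, and computes
    a battery of background features: band-wise spectral power, range-EEG
    margins, interburst-interval statistics, amplitude moments, spectral
    shape, Higuchi fractal dimension, brain symmetry index and
    inter-hemispheric coherence.  Couples these with early clinical and
    qualitative-EEG predictors in depth-regularised random-forest and
    gradient-boosting models evaluated under nested leave-one-out
    cross-validation with late logit fusion, Matthews-correlation model
    comparison (Hotelling-Williams test) and bootstrap confidence
    intervals.  A class-conditional synthetic cohort generator (clinical
    tables, burst-suppression EEG, seizure annotations) makes the full
    pipeline testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
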