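Package: atenet
Title: Adaptive Temporal Encoder Networks for EEG Cognitive-State
    Classification and Health-Intervention Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying cognitive states (high
    cognitive load, mental fatigue, stress, alertness, low alertness) from
    multichannel EEG and mapping predictions to health-intervention
    recommendations. Provides EDF and plain-text fixture ingestion,
    zero-phase band-pass filtering, resampling, z-score normalization and
    windowing; Welch power-spectral-density band features and event-related
    potential averaging; a cascade data-augmentation policy (time shift,
    Gaussian noise, time warp, channel dropout); an adaptive temporal
    encoder network combining per-step dynamic attention, temporal
    convolutions, residual layer-normalized blocks, multi-scale feature
    integration and hierarchical attention pooling, with a hand-written
    backward pass and Adam training loop; subject-wise splitting and
    10-fold cross-validation; and a class-conditional synthetic EEG cohort
    generator with band-power and ERP class signatures for fully
    reproducible experiments without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
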