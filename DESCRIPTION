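Package: sarcscreen
Title: Multimodal Wearable-Sensor Analysis for Sarcopenia Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for sarcopenia screening from
    coupled surface electromyography (sEMG) and piezoelectric strain
    recordings acquired during maximal voluntary grip contractions.
    Provides a motor-unit-based synthetic cohort generator with
    sarcopenia-like neuromuscular alterations, signal conditioning and
    spectral descriptives (median frequency, STFT spectrograms, SNR), the
    nine-feature Hudgins + wavelet engineering stage with MVC
    normalization, a three-stream CNN-LSTM fusion classifier with
    classical baselines, subject-level cross-validation and ROC analysis,
    permutation-sampling Shapley attributions, and an AWGS-2019 rule
    engine for ground-truth screening labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    signal,
    e1071,
    randomForest,
    Rtsne,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    cluster,
    withr
Config/testthat/edition: 3
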