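Package: gazelapse
Title: Predicting Attention Lapses from Eye-Movement Recordings with a
    Hybrid Convolutional-Recurrent Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete pipeline for predicting control forgetting (attention
    lapses of radar air-traffic controllers) from head-mounted eye-tracker
    recordings.  Raw 100 Hz gaze streams are repaired, cut into overlapping
    5-second windows, segmented into fixations, saccades and blinks, and
    summarised by 44 oculomotor metrics (23 time-related, 21
    time-independent).  Sequences of six consecutive windows are classified
    by a dual-branch network: a convolutional feature extractor spliced with
    the raw time-related features feeds a three-layer LSTM, a second
    convolutional branch handles the time-independent features, and a fused
    softmax head outputs the lapse probability.  The network, its Adam
    optimiser and Kaiming initialisation are implemented in base R matrix
    algebra.  Includes a seeded synthetic scanpath generator with annotated
    lapse episodes, logistic-regression and single-branch ablation
    baselines, and a five-fold cross-validation benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
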