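Package: vigileye
Title: Classification of Sleep-Deprivation-Induced Performance Impairment
    from Eye- and Face-Tracking Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether remote eye tracking and facial
    action-unit tracking can classify psychomotor vigilance task (PVT)
    performance as normal or impaired during sustained wakefulness.
    Provides a synthetic-study generator with known ground truth (gaze
    streams, 21 facial-channel probability series, PVT event logs),
    blink and dispersion-based (I-DT) fixation detection, PVT lapse
    scoring with per-subject Euclidean normalization, a group-level
    impairment threshold derived from one-way ANOVA with Tukey-Kramer
    post-hoc comparisons, Welch t and Fisher-score feature statistics,
    five feature-selection regimes (all-inclusion, significance filter,
    Fisher filter, sequential forward selection, genetic algorithm), and
    a 14-classifier leave-one-subject-out evaluation grid with balanced
    undersampling and geometric-mean balanced accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    class,
    e1071,
    jsonlite,
    nnet,
    rpart,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
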