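Package: symprof
Title: Symptom Profiling for Depression Severity Prediction from Smartphone Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for predicting depressive symptoms and
    three-level depression severity (none/mild, moderate, severe) from
    smartphone passive-sensing data and PHQ-9 ecological momentary
    assessments (EMAs). Implements EMA quality filtering (reliability trap
    question, Speeder Index), daily aggregation and per-item linear
    interpolation of PHQ-9 scores, sensor-stream cleaning (range checks,
    density-based GPS outlier removal, gap imputation, per-participant
    Box-Cox transforms), daily behavioural feature extraction, and the
    symptom-profile representation: a per-day nine-element vector formed as
    the Hadamard product of per-participant symptom significance
    (item-total correlations) and model-predicted symptom probabilities.
    Severity classifiers are evaluated with leave-one-subject-out
    cross-validation, SMOTE class balancing, and weighted multi-class
    metrics. A seeded synthetic-cohort simulator with known latent symptom
    structure provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    tools,
    geosphere,
    xgboost,
    ranger,
    e1071,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
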