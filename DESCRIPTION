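Package: binoculaR
Title: Binocular Eye-Movement Descriptor Extraction and Dyslexia Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates binocular horizontal eye-position recordings for
    vergence, saccade and reading protocols; extracts physiologic oculomotor
    descriptors (latency, phasic and total amplitude, duration, peak and
    average velocity, post-movement disconjugate drift, regressive-saccade
    rate) by velocity-threshold event detection on the vergence and conjugate
    channels; aggregates them into per-subject feature tables; and evaluates
    two downstream analyses on those tables: cross-validated dyslexia
    classification over a roster of linear and non-linear models with
    label-permutation significance testing, and reading-speed regression with
    fold-internal correlation-based feature selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    class,
    e1071,
    kernlab,
    nnet,
    rpart,
    randomForest,
    glmnet,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
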