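Package: molUQ
Title: Uncertainty Quantification and Uncertainty-Guided Active Learning
    for Molecular Property Regression
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluation framework for uncertainty quantification (UQ) in
    QSAR-style molecular property regression. Implements seven per-molecule
    uncertainty estimators (quantile gradient boosting, deep ensembles,
    Monte Carlo dropout, mean-variance estimation, deep evidential
    regression with a Normal-Inverse-Gamma head, a union approach, and
    k-nearest-neighbour density in descriptor or embedding space) plus a
    consensus combination, under a common estimate contract. Provides four
    complementary evaluation metrics - expected normalized calibration
    error (ENCE), the error-uncertainty Spearman correlation, an
    out-of-distribution correlation against similarity-to-training, and a
    leave-bin-out delta-error/delta-uncertainty correlation built on PCA
    percentile bins - together with Butina-style sphere-exclusion
    clustering and group-distance diagnostics. A single-iteration
    pool-based active-learning experiment with linear uncertainty-weighted
    sampling, random/diversity/OOD-only baselines, paired one-sided
    t-tests and grid summaries completes the pipeline. A clustered
    synthetic-data generator with a known nonlinear teacher and known
    heteroscedastic noise makes every stage testable without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
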