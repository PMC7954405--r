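Package: AcuityTransfer
Title: Multi-Modal Recurrent Models and Transfer Learning for ICU Acuity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting hospital discharge disposition of intensive
    care patients from routinely charted vital signs and wrist-actigraphy
    activity counts. Provides a synthetic ICU cohort generator driven by a
    latent severity process, hourly resampling and development-set-only
    preprocessing (percentile capping, forward-fill imputation,
    standardization) of vital-sign streams, nine-statistic 24-hour actigraphy
    feature extraction, single-branch and parallel two-branch gated recurrent
    unit (GRU) classifiers trained with Adam and early stopping, a
    partial-weight transfer-learning protocol from a large vitals-only source
    cohort to a small multi-modal target cohort, and repeated stratified
    cross-validation with percentile confidence intervals plus chronological
    holdout evaluation with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    arrow
Config/testthat/edition: 3
RoxygenNote: 7.3.3
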