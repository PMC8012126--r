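Package: ecgilfs
Title: ECG-Based Recognition of the Impulse of Love at First Sight
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for classifying the impulse of love at
    first sight (ILFS) from single-lead electrocardiogram recordings.
    Provides a trial-structured synthetic ECG and self-report generator,
    wavelet soft-threshold denoising, Pan-Tompkins R-peak detection,
    extraction of 25 heart-rate-variability features (time-domain,
    Poincare/nonlinear including Lempel-Ziv complexity, and Lomb-Scargle
    frequency-domain), median-absolute-deviation outlier screening,
    rating-based trial labeling, sequential floating forward feature
    selection inside nested 10-fold cross-validation, five standard
    classifiers, and full sensitivity/specificity/F1/AUC/accuracy
    reporting with per-feature rank tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    randomForest,
    rpart,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
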