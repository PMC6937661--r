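Package: wellcast
Title: One-Day-Forward Wellness Forecasting from Short Single-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forecasts next-day self-evaluated wellness of elderly subjects
    from short (20-25 s) single-lead electrocardiogram recordings. Provides a
    synthetic cohort generator with a tunable link between daily heart rate
    and next-day wellness, exponentially weighted moving-average denoising,
    sliding-window segmentation with min-max scaling, rank-based inverse-normal
    (Fisher-Yates) normalization and dichotomization of ordinal health-index
    scores with one-day-forward label alignment, four classifier families
    (LSTM, bidirectional LSTM, single-hidden-layer neural network, RBF-kernel
    support vector machine), and a grouped k-fold cross-validation evaluation
    suite with recall, precision, false-positive rate, accuracy, F-score and
    ROC/AUC reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
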