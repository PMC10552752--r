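Package: falldet
Title: Wearable Fall Detection with Hybrid Metaheuristic Feature Selection
    and a Tamper-Evident Event Ledger
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting falls of elderly subjects
    from multichannel wearable-sensor records (distance, pressure level,
    heart-rate variability, blood sugar, SpO2, accelerometer). Provides a
    seeded synthetic-data generator emulating the cStick device schema,
    cleaning and train/test splitting, feature extraction (statistical
    moments, lagged autocorrelation, PCA with eigenvalue thresholding), a
    hybrid teaching-learning/spring-search metaheuristic (HTLSS) for wrapper
    feature selection and hyperparameter tuning, a three-branch neural
    ensemble (LSTM, HTLSS-tuned 1-D CNN, gated RNN) with soft-vote fusion,
    a nine-metric confusion-matrix evaluation suite with ROC curves, and a
    local hash-chained ledger of fall events with severity-based alert
    routing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
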