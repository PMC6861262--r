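Package: swarmdx
Title: Swarm-Intelligence Reader Consensus and Human-in-the-Loop
    Diagnostic Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates real-time swarm consensus among diagnostic readers
    (a closed-loop agent model with squared-impulse interpolation over
    probability bins), computes crowd aggregation baselines (mean and
    majority vote), threshold classification with confusion-matrix
    diagnostics, the standard probabilistic accuracy metrics (percent
    correct, MAE, Brier score, rank AUC, F1, sensitivity, specificity)
    with percentile-bootstrap confidence intervals, and a confidence-band
    deferral scheme that routes low-confidence machine diagnoses to a
    human swarm, including a deferral-fraction sensitivity sweep. A
    calibrated logit-normal synthetic-data generator reproduces
    study-like reader panels and machine operating points so the full
    pipeline is testable without access to the original per-case data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
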