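Package: spo2burden
Title: Overnight Oximetry Desaturation Burden Metrics and Postoperative
    Respiratory Depression Risk Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing sleep-apnea severity from overnight
    pulse-oximetry (SpO2) alone and for evaluating how well the resulting
    measures predict postoperative respiratory depression. Implements
    preprocessing of quantized 3 Hz SpO2 traces (edge trimming, invalid-sample
    marking, median filtering, eligibility rules), derivative-based detection
    of desaturation episodes with >= 3% drops, per-episode desaturation
    burdens relative to a 100-second pre-recovery baseline, and seven
    overnight summary measures: entropy and standard deviation of the SpO2
    signal, below-average burden, the mean, standard deviation and entropy of
    normalized episode burdens, and the overall nocturnal desaturation burden.
    Includes a synthetic overnight-cohort generator with known ground truth, a
    repeated stratified-holdout logistic-regression harness reporting AUC,
    sensitivity and specificity with confidence intervals, and Pearson
    correlation utilities with Fisher-interval sex comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    glmnet,
    pROC,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
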