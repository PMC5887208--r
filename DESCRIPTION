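Package: adescreen
Title: Stratified Adverse Drug Event Screening with Association Rules and
    the Proportional Reporting Ratio
Version: 1.0.0
Authors@R:
    person("adescreen", "developers", email = "adescreen@example.org",
           role = c("aut", "cre"))
Description: Signal detection for spontaneous reporting system (SRS) data
    stratified by primary disease. Screens (drug, primary disease,
    adverse event) triples with association-rule statistics (support,
    confidence, lift, conviction) mined under apriori pruning, and with
    the conventional stratified proportional reporting ratio (PRR) plus
    Yates-corrected chi-squared detector, then compares the two
    detectors head-to-head via sensitivity, specificity, Youden's index,
    predictive values, ROC/AUC, and the regression of log lift on PRR
    signal intensity. Includes a JADER-style four-table reader
    (DEMO/DRUG/REAC/HIST), a synthetic SRS generator with injected
    ground-truth relative risks, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
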