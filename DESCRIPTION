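Package: ruleout
Title: Simulation and Evaluation of Rule-Out Triage Workflows in Cancer
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Retrospective evaluation framework for semiautonomous
    "rule-out" triage devices in breast cancer screening. Converts
    longitudinal screening records into breast- and examination-level
    outcome labels (negative, screening benign, diagnostic benign,
    pathology benign, high risk, malignant, interval cancer), selects a
    rule-out score threshold at a target cancer sensitivity, simulates the
    device-first reading workflow, and computes prevalence-rebalanced
    screening metrics (cancer detection rate, rule-out rate,
    false-positive callback and benign biopsy reductions, specificity,
    relative and combined workflow sensitivity) with stratified bootstrap
    confidence intervals, paired noninferiority tests, and one-sided
    superiority p values by confidence-interval inversion. Includes a
    synthetic cohort generator with known ground truth and closed-form
    metric expectations so every pipeline stage is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
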