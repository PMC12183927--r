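Package: bbadx
Title: Diagnostic Performance Evaluation of Blood Biomarkers for Amyloid Pathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating plasma biomarkers of Alzheimer's disease
    (pTau217, pTau181, Abeta42, Abeta40, NfL) against a CSF-defined amyloid
    reference standard in a memory-clinic cohort. Implements CSF cut-off based
    amyloid and AT classification, normality-routed two-group contrasts with
    Cohen's d and FDR control, from-scratch ROC machinery with DeLong AUC
    inference, Youden and dual 95%-sensitivity/specificity cut-off selection,
    prevalence-dependent predictive values, all-pairs DeLong AUC comparison,
    per-biomarker logistic and MMSE linear models, a Monte-Carlo robustness
    simulation under multiplicative measurement noise, and a moment-matched
    synthetic cohort generator so the full pipeline is testable without
    subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
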