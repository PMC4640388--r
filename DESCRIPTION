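Package: ydrisk
Title: Your Disease Risk Relative-Risk Score for Coronary Heart Disease and
    Its Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the Your Disease Risk (YDR) multiplicative
    relative-risk score for 10-year coronary heart disease: a consensus-based
    risk-factor table (relative risks and population prevalences), the
    prevalence-normalised scoring equation, and the seven ordered risk
    categories. Also provides the validation battery used to evaluate such
    health risk appraisal tools against a cohort with a binary 10-year
    outcome: category calibration via closed-form and logistic-model odds
    ratios (crude, age-adjusted, and age-stratified), discrimination via
    tie-corrected concordance statistics with Hanley-McNeil or DeLong
    confidence intervals, comparison of c-statistics between age strata, and
    a synthetic-cohort generator emulating a nurses'-cohort structure with
    known ground truth for calibration and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
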