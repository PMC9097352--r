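Package: mcitext
Title: Predicting Mild Cognitive Impairment from Free-Text Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying patients at risk of mild
    cognitive impairment (MCI) from routinely collected clinical notes in the
    absence of standardized screening. Provides a dictionary-driven concept
    extractor with gap-tolerant phrase matching, cross-patient boilerplate
    detection based on shared 180-character contexts, cohort construction with
    index dates, exclusions and 1:1 matching, feature construction (binary
    concept indicators plus aggregate symptom/behavior/forgetfulness sums and
    demographics), an L1-penalized logistic prediction model with tenfold
    cross-validated shrinkage, and screening-style evaluation (ROC/AUC,
    sensitivity, specificity, PPV, NPV across probability cutoffs). Ships a
    synthetic clinical-corpus generator with planted ground truth so every
    stage can be tested without protected health information.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
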