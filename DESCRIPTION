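Package: bariclaims
Title: Validation of Claims-Based BMI Phenotyping Algorithms for
    Bariatric Surgery Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to develop and validate administrative-claims-based
    phenotyping algorithms for severe obesity and body mass index (BMI)
    categorization among bariatric surgery patients. Provides
    dictionaries mapping ICD-9-CM (V85.x, 278.xx) and ICD-10-CM (Z68.x,
    E66.xx) weight-related diagnosis codes to ordered BMI categories, a
    synthetic linked claims+EHR data generator with a configurable
    coding-fidelity kernel and an analytic oracle for expected
    agreement, nested cohort construction with temporal windows and
    proximity rules, the severe-obesity and BMI-categorization
    algorithms with their sensitivity-analysis variants, and validation
    statistics (per-level sensitivity, specificity, PPV, NPV, and
    weighted Cohen's kappa with asymptotic or bootstrap confidence
    intervals), including small-cell suppression for de-identified
    reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
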