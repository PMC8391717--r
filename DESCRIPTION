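Package: clical
Title: Weighted Clinical Scoring and Survival-Forest Validation for
    Melanoma Immunotherapy Cohorts
Version: 0.1.0
Authors@R:
    person("INT-NA", "Pipeline Maintainers", role = c("aut", "cre"),
           email = "maintainers@example.org")
Description: Implements the CLICAL clinical categorization algorithm: a
    weighted categorical score over seven baseline clinical variables
    (age group, BRAF status, prior targeted therapy, LDH category,
    neutrophil-lymphocyte ratio, eosinophil status, CNS metastases)
    that stratifies metastatic melanoma patients treated with immune
    checkpoint inhibitors into five prognostic signatures.  Ships
    native Kaplan-Meier, Nelson-Aalen, Mantel-Cox log-rank, Cox
    proportional-hazards (Efron ties) and Harrell concordance
    estimators, a log-rank-split survival random forest with
    out-of-bag tuning for machine-learning validation of the score,
    time-dependent IPCW ROC/AUC and Brier prediction error, and a
    seeded synthetic-cohort simulator calibrated to published cohort
    marginals and signature-level hazards so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
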