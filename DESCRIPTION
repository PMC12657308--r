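Package: ckdphen
Title: Computable Phenotyping of Advanced Chronic Kidney Disease from
    Longitudinal Hospital Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for identifying advanced chronic kidney
    disease (CKD) from routine electronic health records in a
    healthcare-integrated biobanking (HIB) setting: CKD-EPI 2009 eGFR
    estimation (and its closed-form inversion), KDIGO acute kidney injury
    and reverted-AKI detection on creatinine time series, assembly of the
    admissionHIB / historyHIB / historyCKD predictor profiles, rule-based
    (eGFR threshold, ICD-10 codes, discharge-summary flag) and model-based
    (logistic regression with Youden-index cutoffs, random-forest
    silver-standard labeler) classifiers, and a validation harness with
    confusion-matrix metrics, Wilson confidence intervals, ROC/PR curves
    and Cohen's kappa, plus a synthetic longitudinal EHR generator with
    known ground truth so the whole pipeline is testable without access to
    restricted hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ranger,
    glmnet,
    pROC
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
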