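Package: faimsvoc
Title: Cross-Validated Classification of FAIMS Volatile Organic Compound
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for faecal volatile organic compound (VOC)
    profiles measured by field asymmetric ion mobility spectrometry (FAIMS).
    Ingests two-polarity dispersion matrices (51 dispersion-field steps by 512
    compensation-voltage steps per polarity), removes uninformative background
    pixels, and classifies clinical groups by tenfold cross-validation with
    rank-sum feature selection nested inside each training fold, comparing
    random forest, Gaussian process, support vector machine and sparse
    logistic regression classifiers. Reports pooled out-of-fold ROC curves
    with AUC, bootstrap confidence intervals and permutation p-values, Youden
    operating points, predictive values, and feature-location maps. Includes
    a synthetic dispersion-plot generator with planted class effects and a
    cohort metadata simulator so the whole pipeline is testable without
    instrument data, plus utilities to reconstruct integer confusion matrices
    from published sensitivity/specificity summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    e1071,
    kernlab,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
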