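Package: cactusflip
Title: Flip-Based Explainable Classification of Unbalanced Biomarker Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for stratifying haematuria patients into sick and healthy
    groups from multi-biomarker panels. Implements a two-state ("flip")
    abstraction of quantitative biomarkers using ROC-derived (Youden) cut-offs,
    a conditional-probability cost-function classifier (CACTUS) that is robust
    to class imbalance, rank-based biomarker importance scores, and a
    benchmarking harness with k-means silhouette scans, single-marker logistic
    regression with spline selection, decision trees and random forests under
    repeated stratified cross-validation, and a LIME-style local explainer.
    Includes a synthetic cohort generator that emulates the unbalanced
    structure of real haematuria clinic populations (gender imbalance,
    right-skewed marker distributions, detection limits, missingness) so the
    whole pipeline is testable without access to patient data, plus balanced
    accuracy, chi-squared and McNemar model-comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    cluster,
    rpart,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
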