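Package: msapipe
Title: Microsatellite Analysis of Urine and Blood for Bladder Cancer
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for calling loss of heterozygosity (LOH) from matched
    blood/urine capillary-electrophoresis peak heights at short tandem
    repeat (STR) markers, and for modelling binary marker profiles with a
    staged machine-learning pipeline: a stochastic gradient boosting base
    model, a marker-burden engineered feature, random-forest
    proximity-based outlier removal, minority-class up-sampling,
    permutation-importance marker selection, and a stacked ensemble
    combining one-class support vector machines with elastic-net logistic
    regression. Includes a synthetic cohort generator emulating the
    matched blood/urine study design, per-marker cut-off calibration from
    healthy panels, sample acceptance rules, and evaluation utilities
    (ROC/AUC, confusion metrics, PCA views).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    randomForest,
    e1071,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
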