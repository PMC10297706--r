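Package: retinorank
Title: Ranking Clinical Risk Factors for Diabetic Retinopathy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Ranks tabular clinical risk factors for a binary diabetic
    retinopathy outcome by two complementary routes: independent two-sample
    t-tests and retrain-based Shapley feature attributions. Rankings are
    converted to integer weights, pruned by a greedy cross-validated-AUC
    elimination scan per classifier family (k-nearest neighbours, decision
    tree, support vector machine, logistic regression, Gaussian naive
    Bayes), averaged over repeats into an ensemble ranking, and the best
    ranking prefix is used for final held-out evaluation (sensitivity,
    specificity, AUC, accuracy, ROC). Includes a synthetic cohort generator
    with planted logistic effects, SMOTE minority oversampling, and a fully
    reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    class
Config/testthat/edition: 3
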