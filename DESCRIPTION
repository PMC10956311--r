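Package: pdxms
Title: Morphometric and Statistical Modelling of Breast Cancer PDX Engraftment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing predictors of patient-derived xenograft (PDX)
    engraftment from digitised breast-cancer histology and clinicopathological
    records. Provides a synthetic generator for tissue-class label maps and
    patient cohorts with known ground truth; tumour-region delineation on patch
    label grids and the intratumoral tissue proportions (adipose, background,
    necrosis, TDLU, stroma, invasive carcinoma and lymphocyte area fraction, on
    a x10,000 scale); exploratory group comparisons; logistic regression fitted
    by iteratively reweighted least squares with Wald inference, univariate
    screening and backward stepwise elimination by AIC; a CART classifier with
    Gini splitting, cost-complexity pruning, cross-validated error and variable
    importance; and model evaluation by ROC/AUC with bias-corrected accelerated
    (BCa) bootstrap confidence intervals, Youden-index cutoff selection and
    predictive values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    boot,
    MASS,
    pROC,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
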