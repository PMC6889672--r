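Package: irfmda
Title: Random-Forest Prediction of miRNA-Disease Associations with
    Permutation-Importance Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores candidate miRNA-disease associations with a random-forest
    regression model trained on integrated similarity features. Implements
    MeSH-style DAG semantic similarity of diseases (two contribution models),
    Gaussian interaction profile kernel similarity of diseases and miRNAs,
    similarity integration, balanced negative sampling, out-of-bag
    permutation variable importance for feature selection, and ranking-based
    cross-validation (global/local leave-one-out and repeated k-fold) with
    ROC/AUC summaries. Includes a block-structured synthetic data generator
    so the whole pipeline can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
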