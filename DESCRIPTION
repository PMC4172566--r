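Package: chemoclass
Title: Cancer Drugs as Classifiers: Penalized GLM Analysis of Cell
    Discrimination, Chemosensitivity, and Drug-Pair Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Treats cancer drugs as statistical classifiers over molecular
    markers. Provides a three-part analysis pipeline: (I) discriminating
    cancerous from healthy single cells with L2-regularized logistic
    regression under nested cross-validation, with ROC/AUC curves, shuffle
    controls, and gene-count and cell-count learning curves; (II) modelling
    drug chemosensitivity (-log GI50) across cell-line panels as an
    L1-penalized linear function of gene expression with leave-one-out R2
    and two-gene sensitivity heatmaps; (III) exhaustively searching drug
    pairs for two-feature compound classifiers that discriminate cell
    populations better than either drug alone. Includes synthetic-data
    generators that emulate the statistical structure of single-cell
    expression sets and cell-line drug-response panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
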