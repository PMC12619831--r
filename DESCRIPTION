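Package: metabopanel
Title: Biomarker Panel Discovery for Targeted Urinary Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for quantitative urinary-metabolomics biomarker
    discovery in diabetic kidney disease: preprocessing of absolute metabolite
    concentration tables (missingness filtering, limit-of-detection imputation,
    creatinine normalization, log transformation, Pareto scaling), nonparametric
    univariate statistics with false-discovery-rate control, PLS-DA with VIP
    scores and permutation validation, LASSO-based logistic panel construction
    with stepwise refitting and Monte-Carlo cross-validated ROC curves, a
    genetic-algorithm wrapper around elastic-net logistic regression with nested
    cross-validation, stability selection and bootstrap performance estimation,
    and hypergeometric over-representation analysis of selected metabolites.
    Includes a synthetic-data generator emulating a three-group case-control
    design so every stage is testable without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
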