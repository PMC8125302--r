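Package: senopanel
Title: Blood Immunosenescence Biomarker Panels for Age, Frailty and
    Tumor Immune Infiltrate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks circulating immune and senescence biomarkers by their
    ability to separate patient groups (chronological age, G8-based clinical
    frailty, tumor immune infiltrate categories) using a composite of
    ROC-AUC, Wilcoxon rank-sum p-value and standardized log fold-change with
    the AUC weighted double, exhaustively searches all one- to
    three-biomarker panels scored by a linear discriminant classifier
    (resubstitution accuracy and residual-probability loss), and categorizes
    tumor immune infiltration from stromal TIL percentages and CD3/CD8
    densities. Includes a synthetic cohort generator with planted group
    effects and block-wise missingness so the whole pipeline can be
    exercised and validated without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
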