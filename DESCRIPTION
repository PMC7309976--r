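Package: radsig
Title: CT Radiomics Signatures for Tumor Subtype Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating CT radiomics signatures that
    discriminate triple-negative from non-triple-negative breast cancer.
    Implements 3D radiomic feature extraction from tumor volumes of interest
    (first-order, morphological, and grey-level co-occurrence, run-length,
    size-zone, neighbourhood grey-tone difference and dependence texture
    features), SVM-based recursive feature elimination, LASSO-penalized
    logistic signature fitting with cross-validation, linear radiomics
    scoring, and diagnostic evaluation (ROC/AUC with DeLong intervals,
    Youden cutoffs, predictive values with Clopper-Pearson intervals,
    intraclass correlation for delineation reproducibility, and baseline
    group comparisons). Includes a synthetic CT cohort generator with
    class-specific lesion texture and shape and simulated observer
    delineations, and a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    glmnet,
    e1071,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
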