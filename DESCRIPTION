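Package: ifcseq
Title: Predicting Single-Cell Expression Profiles for Imaging Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts per-cell gene-expression profiles for imaging flow
    cytometry (IFC) experiments by co-registering an independent single-cell
    transcriptomics (SCT) experiment through surface markers shared by both
    modalities. Provides the SCT preprocessing pipeline (species selection,
    cell and gene filters, dispersion-based highly-variable-gene selection,
    log transformation, one-vs-rest marker-gene ranking), per-modality
    min-max marker co-registration with rectangular gating, a multi-output
    random-forest regression model (mean-absolute-error splits) with
    per-tree ensemble uncertainty and a linear baseline, a label-free mode
    that regresses marker values from 32x32 brightfield images with a
    residual convolutional network, the full evaluation suite (per-cell and
    per-gene correlations, RMSE, population expression profiles,
    transcriptional similarity with Fisher-transform confidence intervals,
    bootstrap error bars), and a synthetic paired-modality data generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
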