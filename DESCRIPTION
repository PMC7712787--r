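Package: nacresp
Title: Early Prediction of Neoadjuvant Chemotherapy Response from Longitudinal PET/MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for early prediction of pathological
    response to neoadjuvant chemotherapy in advanced breast cancer from paired
    baseline and interim PET and diffusion-weighted MRI. Provides a seeded
    synthetic phantom cohort generator (ellipsoidal tumours in 3D voxel grids,
    Rician DWI noise, multiplicative PET noise), conventional parameter
    extraction (SUVmax, metabolic tumour volume, total lesion glycolysis, mean
    apparent diffusion coefficient, and their percent changes), ROC analysis
    with DeLong confidence intervals and Youden-optimal cutoffs, molecular
    subtype subgroup filtering, a small convolutional neural network classifier
    on 64x64 lesion crops with rotation-based augmentation of the minority
    class and k-fold cross-validation, and an orchestrating, fully seeded
    pipeline that writes NIfTI volumes, CSV tables and a JSON report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
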