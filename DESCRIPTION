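Package: petmoco
Title: Frame-by-Frame Motion Correction and Flow Quantification for Dynamic Cardiac PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for inter-frame rigid motion correction of dynamic cardiac
    PET and its downstream effect on myocardial blood flow (MBF) and flow
    reserve (MFR) quantification. Provides a 4D digital cardiac phantom with
    known kinetics and ground-truth motion; per-frame translation simulation
    including bootstrap resampling of operator corrections and early-frame
    myocardial creep; a dual-input 3D residual convolutional regressor that
    predicts per-frame translation vectors against a summed-late-frame
    reference, trained with site-wise grouped cross-validation; a classical
    normalized cross-correlation registration baseline; one-tissue-compartment
    kinetic modelling of MBF/MFR; and the evaluation statistics used in
    dynamic-PET motion-correction studies (per-axis translation errors,
    Bland-Altman limits, Lin's concordance correlation with confidence
    intervals and Fisher-z comparison, the Pitman-Morgan paired-variance test,
    and DeLong AUC estimation and comparison).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
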