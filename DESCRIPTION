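Package: habitatbm
Title: Habitat and Peritumoral Radiomics for Intracranial Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for habitat-peritumoral radiomics on 3D lesion
    MRI. Provides bias-field correction, isotropic resampling, voxel-wise
    local feature maps, population-level K-means habitat discovery with
    validity-index model selection and multi-seed stability, physical-distance
    peritumoral ring construction, an IBSI-style radiomic feature bank
    (shape, first-order, GLCM/GLRLM/GLSZM/NGTDM/GLDM over a wavelet/LoG/
    intensity-transform filter bank), a five-stage feature-selection cascade
    (significance filter, correlation pruning, recursive elimination, mRMR,
    LASSO), clinical covariate modelling with PNI/SIRI indices, six machine
    learning classifiers, and a full evaluation suite (DeLong AUC inference,
    Hosmer-Lemeshow calibration, decision curves, Shapley attribution,
    nomogram export). A synthetic cohort generator with known habitat
    structure and clinical effects makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Rcpp,
    glmnet,
    xgboost,
    ranger,
    randomForest,
    e1071,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    cluster,
    withr
Config/testthat/edition: 3
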