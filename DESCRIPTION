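Package: kinhet
Title: Kinetic-Heterogeneity Subregion Analysis and Radiomics for Breast DCE-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Voxel-wise classification of dynamic contrast-enhanced MRI
    time-intensity curves into persistent, washout and plateau subregions;
    kinetic-heterogeneity entropy and related per-tumor parameters; a
    radiomic feature extractor (shape, first-order, GLCM, GLDM, GLRLM,
    GLSZM over an original + LoG + wavelet image bank); and LASSO-logistic
    Radscore models with ROC, Youden operating metrics and decision-curve
    analysis. A synthetic DCE phantom and cohort generator with known
    ground truth drives the whole pipeline, so every stage is testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
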