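Package: PCLassoPET
Title: Voxel-Based PCA and LASSO Analysis of Parametric Brain PET Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Data-driven, voxel-based analysis of ROI-restricted parametric
    brain PET images in a common labeled template space. Identifies voxel
    covariance patterns with principal component analysis, combines pattern
    scores and clinical covariates into L1-regularized (LASSO) predictive
    models of clinical disease metrics selected by repeated random-holdout
    cross-validation, and back-transforms fitted models into interpretable
    voxel-weight estimator maps with maximum-intensity-projection rendering.
    Includes a synthetic striatal phantom generator with known planted
    covariance patterns and clinical couplings for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'clinical.R'
    'imaging-io.R'
    'phantom.R'
    'pca.R'
    'lasso.R'
    'cv.R'
    'estimator.R'
    'pipeline.R'
    'utils.R'
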