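#' @import methods
NULL

#' Labeled striatal template
#'
#' A common-space voxel grid with integer ROI labels (0 = background,
#' 1 = putamen, 2 = caudate + ventral striatum). Axes follow the anatomical
#' convention: axis 1 = lateromedial (LM), axis 2 = anteroposterior (AP,
#' increasing index = anterior), axis 3 = inferosuperior (IS, increasing
#' index = superior).
#'
#' @slot labels integer 3D array of ROI labels.
#' @slot voxel_size numeric(3), mm per axis.
#' @slot axes character(3), axis names (fixed to LM/AP/IS).
#' @slot geometry list, provenance of the ROI geometry used to build the
#'   template (empty for templates read from file).
#' @exportClass LabeledTemplate
setClass("LabeledTemplate",
  representation(labels = "array", voxel_size = "numeric",
                 axes = "character", geometry = "list"),
  prototype(axes = c("LM", "AP", "IS"), geometry = list()))

setValidity("LabeledTemplate", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  lv <- unique(as.vector(object@labels))
  if (!all(lv %in% c(0, 1, 2)))
    msg <- c(msg, "label values must be in {0, 1, 2}")
  if (!any(object@labels == 1) || !any(object@labels == 2))
    msg <- c(msg, "both ROIs (labels 1 and 2) must be nonempty")
  if (length(object@voxel_size) != 3L || any(object@voxel_size <= 0))
    msg <- c(msg, "voxel_size must be 3 positive numbers")
  if (length(msg)) msg else TRUE
})

#' Parametric PET image
#'
#' A 3D voxel grid of dimensionless binding-ratio (BR) values, or of raw
#' activity, in common template space.
#'
#' @slot values numeric 3D array.
#' @slot affine numeric 4x4 voxel-to-world matrix.
#' @slot voxel_size numeric(3), mm.
#' @slot subject_id character scalar.
#' @slot side one of "left", "right", "better", "worse" or NA.
#' @slot kind "BR" or "activity"; BR images must be nonnegative.
#' @slot meta list of processing metadata (e.g. reference-region statistics).
#' @exportClass ParametricImage
setClass("ParametricImage",
  representation(values = "array", affine = "matrix", voxel_size = "numeric",
                 subject_id = "character", side = "character",
                 kind = "character", meta = "list"),
  prototype(affine = diag(4), voxel_size = c(1, 1, 1),
            subject_id = NA_character_, side = NA_character_,
            kind = "BR", meta = list()))

setValidity("ParametricImage", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "voxel values must be finite")
  if (identical(object@kind, "BR") && any(object@values < 0))
    msg <- c(msg, "BR images must be nonnegative")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  if (!object@side %in% c("left", "right", "better", "worse", NA_character_))
    msg <- c(msg, "side must be left/right/better/worse or NA")
  if (length(msg)) msg else TRUE
})

#' Subject-by-voxel BR matrix over one ROI
#'
#' Rows are subjects, columns are template voxels of one ROI in fixed
#' lexicographic (i, j, k) order (0-based indices).
#'
#' @slot data numeric N x V matrix.
#' @slot voxel_index integer V x 3 matrix of 0-based template coordinates.
#' @slot roi_label integer ROI label.
#' @slot side character side tag.
#' @slot subject_ids character(N).
#' @exportClass VoxelMatrix
setClass("VoxelMatrix",
  representation(data = "matrix", voxel_index = "matrix",
                 roi_label = "integer", side = "character",
                 subject_ids = "character"))

setValidity("VoxelMatrix", function(object) {
  msg <- character()
  if (ncol(object@data) != nrow(object@voxel_index))
    msg <- c(msg, "data column count must equal voxel_index row count")
  if (nrow(object@data) != length(object@subject_ids))
    msg <- c(msg, "row count must equal length(subject_ids)")
  if (ncol(object@voxel_index) != 3L)
    msg <- c(msg, "voxel_index must have 3 columns")
  if (length(msg)) msg else TRUE
})

#' Planted orthonormal pattern basis for the phantom
#'
#' @slot patterns numeric K x V matrix; rows are mutually orthonormal
#'   voxel-weight vectors over one ROI.
#' @slot kinds character(K) pattern tags.
#' @slot mean_level numeric scalar baseline BR.
#' @slot roi_label integer.
#' @slot voxel_index integer V x 3 (0-based), matching the template ROI.
#' @slot grid_shape integer(3) template grid.
#' @exportClass PlantedBasis
setClass("PlantedBasis",
  representation(patterns = "matrix", kinds = "character",
                 mean_level = "numeric", roi_label = "integer",
                 voxel_index = "matrix", grid_shape = "integer"))

setValidity("PlantedBasis", function(object) {
  msg <- character()
  K <- nrow(object@patterns)
  if (length(object@kinds) != K)
    msg <- c(msg, "one kind tag per pattern required")
  G <- tcrossprod(object@patterns)
  if (max(abs(G - diag(K))) > 1e-8)
    msg <- c(msg, "patterns must be mutually orthonormal")
  g <- which(object@kinds == "global_positive")
  if (length(g) && any(object@patterns[g[1], ] < -1e-10))
    msg <- c(msg, "global_positive pattern must have nonnegative weights")
  if (length(msg)) msg else TRUE
})

#' Voxel-wise PCA decomposition
#'
#' Per-voxel mean, orthonormal PC loadings (rows), subject scores and
#' variance-accounted-for of a subject-by-voxel BR matrix.
#'
#' @slot mean_vector numeric(V) per-voxel mean BR.
#' @slot loadings numeric K x V row-orthonormal matrix.
#' @slot scores numeric N x K matrix.
#' @slot vaf numeric(K) percent variance accounted for, nonincreasing.
#' @slot voxel_index integer V x 3 (0-based).
#' @slot side,roi_label provenance tags.
#' @slot subject_ids character(N).
#' @slot provenance list (subgroup filters etc.).
#' @exportClass PCDecomposition
setClass("PCDecomposition",
  representation(mean_vector = "numeric", loadings = "matrix",
                 scores = "matrix", vaf = "numeric", voxel_index = "matrix",
                 side = "character", roi_label = "integer",
                 subject_ids = "character", provenance = "list"),
  prototype(side = NA_character_, roi_label = NA_integer_,
            provenance = list()))

setValidity("PCDecomposition", function(object) {
  msg <- character()
  K <- nrow(object@loadings)
  if (ncol(object@scores) != K)
    msg <- c(msg, "scores must have one column per loading")
  if (ncol(object@loadings) != length(object@mean_vector))
    msg <- c(msg, "loadings and mean_vector disagree on voxel count")
  if (length(object@vaf) != K)
    msg <- c(msg, "one VAF value per component required")
  if (K > 1 && any(diff(object@vaf) > 1e-8))
    msg <- c(msg, "VAF must be nonincreasing")
  G <- tcrossprod(object@loadings)
  if (max(abs(G - diag(K))) > 1e-6)
    msg <- c(msg, "loadings must be row-orthonormal")
  if (length(msg)) msg else TRUE
})

#' L1-penalized linear model (LASSO fit)
#'
#' Minimizer of 0.5 * RSS + lambda * sum(|beta_j|) with an unpenalized
#' intercept. Coefficients are on the scale of the design handed to the
#' solver; when a standardization record is attached the raw-input scale can
#' be recovered.
#'
#' @slot beta0 numeric intercept (outcome units).
#' @slot betas named numeric coefficients.
#' @slot lambda numeric penalty, >= 0.
#' @slot active_set character names of inputs with nonzero coefficients.
#' @slot standardization list(center, scale, kept) or empty.
#' @slot outcome_name character.
#' @slot n_iter integer coordinate-descent sweeps used.
#' @exportClass LassoModel
setClass("LassoModel",
  representation(beta0 = "numeric", betas = "numeric", lambda = "numeric",
                 active_set = "character", standardization = "list",
                 outcome_name = "character", n_iter = "integer"),
  prototype(standardization = list(), outcome_name = NA_character_,
            n_iter = 0L))

setValidity("LassoModel", function(object) {
  msg <- character()
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (is.null(names(object@betas)) && length(object@betas))
    msg <- c(msg, "betas must be named")
  if (length(msg)) msg else TRUE
})

#' Repeated random-holdout cross-validation result
#'
#' @slot model_type "pclasso", "mean_br" or "constant".
#' @slot lambda_grid numeric grid (empty for reference models).
#' @slot mse_test_mean,mse_test_se numeric per grid value (length 1 for
#'   reference models), outcome units squared.
#' @slot lambda_min numeric selected penalty (NA for reference models).
#' @slot mse_all numeric full-data MSE of the full-data fit at lambda_min.
#' @slot coef_mean,coef_sd named numeric per-input statistics over training
#'   splits at lambda_min (raw input scale).
#' @slot p_values named numeric post-selection p-values (may be empty).
#' @slot retained_terms character active set of the full-data fit.
#' @slot full_model the full-data \linkS4class{LassoModel} (or list for
#'   reference models).
#' @slot n_splits,holdout_fraction,seed CV settings.
#' @slot outcome_name character.
#' @slot metadata list (p-value method, scales, split provenance).
#' @exportClass CVResult
setClass("CVResult",
  representation(model_type = "character", lambda_grid = "numeric",
                 mse_test_mean = "numeric", mse_test_se = "numeric",
                 lambda_min = "numeric", mse_all = "numeric",
                 coef_mean = "numeric", coef_sd = "numeric",
                 p_values = "numeric", retained_terms = "character",
                 full_model = "ANY", n_splits = "integer",
                 holdout_fraction = "numeric", seed = "integer",
                 outcome_name = "character", metadata = "list"),
  prototype(model_type = "pclasso", p_values = numeric(), metadata = list()))

setValidity("CVResult", function(object) {
  msg <- character()
  if (any(object@mse_test_se < 0)) msg <- c(msg, "mse_test_se must be >= 0")
  if (length(object@lambda_grid)) {
    if (length(object@mse_test_mean) != length(object@lambda_grid))
      msg <- c(msg, "one mean MSE per grid value required")
    if (!is.na(object@lambda_min) &&
        !any(abs(object@lambda_grid - object@lambda_min) < 1e-12))
      msg <- c(msg, "lambda_min must be a member of the grid")
  }
  if (length(msg)) msg else TRUE
})

#' Voxel-space PC-LASSO estimator map
#'
#' The beta-weighted sum of PC loadings, v = sum_j beta_j * omega_j, mapped
#' back over the ROI voxels, with covariate coefficients carried separately.
#'
#' @slot v numeric(V) voxel weights.
#' @slot beta0 numeric intercept on the centered-voxel convention.
#' @slot covariate_betas named numeric raw-scale coefficients of non-imaging
#'   inputs.
#' @slot mean_vector numeric(V) per-voxel mean of the source decomposition.
#' @slot voxel_index integer V x 3 (0-based).
#' @slot grid_shape integer(3).
#' @slot provenance list(outcome, lambda, retained terms).
#' @exportClass EstimatorMap
setClass("EstimatorMap",
  representation(v = "numeric", beta0 = "numeric",
                 covariate_betas = "numeric", mean_vector = "numeric",
                 voxel_index = "matrix", grid_shape = "integer",
                 provenance = "list"),
  prototype(covariate_betas = numeric(), provenance = list()))

setValidity("EstimatorMap", function(object) {
  msg <- character()
  if (length(object@v) != nrow(object@voxel_index))
    msg <- c(msg, "v must have one weight per indexed voxel")
  if (length(object@mean_vector) != length(object@v))
    msg <- c(msg, "mean_vector must match v in length")
  if (length(msg)) msg else TRUE
})
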