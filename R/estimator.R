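#' Back-transform a fitted model into a voxel-weight estimator map
#'
#' Assembles v = sum_j beta_j * omega_j over the imaging inputs (PC
#' scores), with coefficients first mapped from the standardized-score
#' scale back to the raw-score scale. Covariate coefficients have no voxel
#' support and are carried separately; the per-voxel mean term is folded
#' into the intercept so that score-space and voxel-space predictions agree
#' exactly.
#'
#' @param decomposition the \linkS4class{PCDecomposition} whose scores were
#'   model inputs.
#' @param lasso_model a \linkS4class{LassoModel} whose imaging inputs are
#'   named PC1, PC2, ... matching the decomposition.
#' @return an \linkS4class{EstimatorMap}.
#' @export
computeEstimator <- function(decomposition, lasso_model) {
  stopifnot(methods::is(decomposition, "PCDecomposition"),
            methods::is(lasso_model, "LassoModel"))
  raw <- rawScaleCoef(lasso_model)
  nm <- names(raw$betas)
  imaging <- grepl("^PC[0-9]+$", nm)
  pcIdx <- as.integer(sub("^PC", "", nm[imaging]))
  retained <- pcIdx[abs(raw$betas[imaging]) > 0]
  if (length(retained) && max(retained) > nrow(decomposition@loadings))
    stopf("model retains PC%d but the decomposition has only %d loadings",
          max(retained), nrow(decomposition@loadings),
          class = "pclasso_validation_error")
  v <- rep(0, ncol(decomposition@loadings))
  iw <- which(imaging)
  for (t in seq_along(iw))
    if (pcIdx[t] <= nrow(decomposition@loadings))
      v <- v + raw$betas[iw[t]] * decomposition@loadings[pcIdx[t], ]
  methods::new("EstimatorMap", v = v, beta0 = raw$beta0,
               covariate_betas = raw$betas[!imaging],
               mean_vector = decomposition@mean_vector,
               voxel_index = decomposition@voxel_index,
               grid_shape = integer(0),
               provenance = list(outcome = lasso_model@outcome_name,
                                 lambda = lasso_model@lambda,
                                 retained = lasso_model@active_set))
}

#' Predict a clinical metric from raw voxel values
#'
#' prediction = beta0 + (f - mean_vector) . v + covariate terms, which
#' equals the score-space prediction of the source model for every subject
#' (the mean-centering convention of the decomposition is applied).
#'
#' @param estimator_map an \linkS4class{EstimatorMap}.
#' @param voxel_vector numeric(V) BR values in the map's voxel order (or a
#'   \linkS4class{VoxelMatrix} row-compatible matrix).
#' @param covariates named numeric of covariate values (raw scale), needed
#'   when the model retained covariates.
#' @return predicted outcome (numeric, one per row of input).
#' @export
predictFromVoxels <- function(estimator_map, voxel_vector,
                              covariates = NULL) {
  F <- if (methods::is(voxel_vector, "VoxelMatrix")) {
    if (!identical(voxel_vector@voxel_index, estimator_map@voxel_index))
      stopf("voxel index mismatch", class = "pclasso_validation_error")
    voxel_vector@data
  } else rbind(voxel_vector)
  if (ncol(F) != length(estimator_map@v))
    stopf("voxel vector length %d does not match the map (%d)",
          ncol(F), length(estimator_map@v),
          class = "pclasso_validation_error")
  pred <- estimator_map@beta0 +
    drop(sweep(F, 2, estimator_map@mean_vector) %*% estimator_map@v)
  cb <- estimator_map@covariate_betas
  cb <- cb[abs(cb) > 0]
  if (length(cb)) {
    if (is.null(covariates) || !all(names(cb) %in% names(covariates)))
      stopf("covariate values required for: %s",
            paste(names(cb), collapse = ", "),
            class = "pclasso_validation_error")
    cov <- rbind(covariates)[, names(cb), drop = FALSE]
    pred <- pred + drop(cov %*% cb)
  }
  pred
}

#' Embed ROI voxel values into the template grid
#'
#' @param values numeric(V) over the indexed voxels.
#' @param voxel_index integer V x 3 0-based coordinates.
#' @param grid_shape integer(3) template grid.
#' @return 3D array, zero outside the ROI.
#' @export
embedVoxels <- function(values, voxel_index, grid_shape) {
  vol <- array(0, grid_shape)
  lin <- 1L + voxel_index[, 1] +
    grid_shape[1] * (voxel_index[, 2] + grid_shape[2] * voxel_index[, 3])
  vol[lin] <- values
  vol
}

.axisNumber <- function(axis) {
  if (is.character(axis))
    match(toupper(axis), c("LM", "AP", "IS"))
  else as.integer(axis)
}

#' Maximum-intensity projections of a voxel-weight map
#'
#' Positive and negative weights are projected separately along the chosen
#' anatomical axis (per-ray maximum of the positive weights, and of the
#' magnitudes of the negative weights); both projections are normalized by
#' the global maximum absolute weight, which is reported.
#'
#' @param weight_map an \linkS4class{EstimatorMap}, or a numeric(V) vector
#'   (then \code{voxel_index} is required), or a 3D array.
#' @param projection_axis 1/2/3 or "LM"/"AP"/"IS".
#' @param grid_shape template grid (required unless \code{weight_map} is an
#'   array).
#' @param voxel_index voxel coordinates when \code{weight_map} is a vector.
#' @return list(positive, negative, norm_factor, axis): two 2D matrices
#'   with values in [0, 1].
#' @export
mipRender <- function(weight_map, projection_axis = "AP",
                      grid_shape = NULL, voxel_index = NULL) {
  if (methods::is(weight_map, "EstimatorMap")) {
    if (is.null(grid_shape)) stopf("grid_shape required for an EstimatorMap")
    vol <- embedVoxels(weight_map@v, weight_map@voxel_index, grid_shape)
  } else if (is.array(weight_map) && length(dim(weight_map)) == 3) {
    vol <- weight_map
  } else {
    if (is.null(voxel_index) || is.null(grid_shape))
      stopf("voxel_index and grid_shape required for a weight vector")
    vol <- embedVoxels(as.numeric(weight_map), voxel_index, grid_shape)
  }
  ax <- .axisNumber(projection_axis)
  if (is.na(ax) || !ax %in% 1:3) stopf("projection axis must be LM, AP or IS")
  keep <- setdiff(1:3, ax)
  pos <- apply(pmax(vol, 0), keep, max)
  neg <- apply(pmax(-vol, 0), keep, max)
  nf <- max(abs(vol))
  if (nf == 0) {
    warnf("all-zero weight map; projections are zero")
    nf <- 1
  }
  list(positive = pos / nf, negative = neg / nf,
       norm_factor = max(abs(vol)), axis = c("LM", "AP", "IS")[ax])
}

#' Write an estimator map as NIfTI plus JSON sidecar
#'
#' @param estimator_map an \linkS4class{EstimatorMap}.
#' @param template the \linkS4class{LabeledTemplate} providing the grid.
#' @param path_prefix output path without extension.
#' @return invisibly, the two file paths.
#' @export
writeEstimatorMap <- function(estimator_map, template, path_prefix) {
  vol <- embedVoxels(estimator_map@v, estimator_map@voxel_index,
                     dim(template@labels))
  img <- methods::new("ParametricImage", values = vol,
                      affine = diag(c(template@voxel_size, 1)),
                      voxel_size = template@voxel_size, kind = "weights")
  writeParametricImage(img, paste0(path_prefix, ".nii.gz"))
  side <- list(beta0 = estimator_map@beta0,
               covariate_betas = as.list(estimator_map@covariate_betas),
               provenance = estimator_map@provenance)
  jsonlite::write_json(side, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paste0(path_prefix, ".nii.gz"), paste0(path_prefix, ".json")))
}
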