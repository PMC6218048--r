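#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: pattern loadings
#' and scores, VAF percentages, per-voxel means, voxel index maps, label
#' arrays and raw voxel data.
#'
#' @param x an object of one of the package's S4 classes.
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patternLoadings", function(x) standardGeneric("patternLoadings"))
#' @rdname accessors
#' @export
setGeneric("patternScores", function(x) standardGeneric("patternScores"))
#' @rdname accessors
#' @export
setGeneric("vaf", function(x) standardGeneric("vaf"))
#' @rdname accessors
#' @export
setGeneric("meanVector", function(x) standardGeneric("meanVector"))
#' @rdname accessors
#' @export
setGeneric("voxelIndex", function(x) standardGeneric("voxelIndex"))
#' @rdname accessors
#' @export
setGeneric("templateLabels", function(x) standardGeneric("templateLabels"))
#' @rdname accessors
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))
#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname accessors
setMethod("patternLoadings", "PCDecomposition", function(x) x@loadings)
#' @rdname accessors
setMethod("patternLoadings", "PlantedBasis", function(x) x@patterns)
#' @rdname accessors
setMethod("patternScores", "PCDecomposition", function(x) x@scores)
#' @rdname accessors
setMethod("vaf", "PCDecomposition", function(x) x@vaf)
#' @rdname accessors
setMethod("meanVector", "PCDecomposition", function(x) x@mean_vector)
#' @rdname accessors
setMethod("meanVector", "EstimatorMap", function(x) x@mean_vector)
#' @rdname accessors
setMethod("voxelIndex", "VoxelMatrix", function(x) x@voxel_index)
#' @rdname accessors
setMethod("voxelIndex", "PCDecomposition", function(x) x@voxel_index)
#' @rdname accessors
setMethod("voxelIndex", "PlantedBasis", function(x) x@voxel_index)
#' @rdname accessors
setMethod("voxelIndex", "EstimatorMap", function(x) x@voxel_index)
#' @rdname accessors
setMethod("templateLabels", "LabeledTemplate", function(x) x@labels)
#' @rdname accessors
setMethod("imageValues", "ParametricImage", function(x) x@values)
#' @rdname accessors
setMethod("voxelData", "VoxelMatrix", function(x) x@data)

#' @describeIn accessors coefficients of a LASSO fit (intercept first).
#' @param object a \linkS4class{LassoModel}.
#' @param ... ignored.
#' @export
setMethod("coef", "LassoModel", function(object, ...) {
  c("(Intercept)" = object@beta0, object@betas)
})

setMethod("show", "LabeledTemplate", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabeledTemplate %dx%dx%d voxels (%.3g mm)\n", d[1], d[2], d[3],
              object@voxel_size[1]))
  cat(sprintf("  putamen: %d voxels; caudate+VS: %d voxels\n",
              sum(object@labels == 1), sum(object@labels == 2)))
})

setMethod("show", "ParametricImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("ParametricImage [%s] subject=%s side=%s %dx%dx%d\n",
              object@kind, object@subject_id, object@side, d[1], d[2], d[3]))
})

setMethod("show", "VoxelMatrix", function(object) {
  cat(sprintf("VoxelMatrix: %d subjects x %d voxels (ROI %d, side %s)\n",
              nrow(object@data), ncol(object@data), object@roi_label,
              object@side))
})

setMethod("show", "PCDecomposition", function(object) {
  cat(sprintf("PCDecomposition: %d PCs over %d voxels, %d subjects\n",
              nrow(object@loadings), ncol(object@loadings),
              nrow(object@scores)))
  k <- min(5L, length(object@vaf))
  cat("  VAF (%):", paste(sprintf("%.1f", object@vaf[seq_len(k)]),
                          collapse = " "), "\n")
})

setMethod("show", "LassoModel", function(object) {
  cat(sprintf("LassoModel lambda=%.4g, active set: %s\n", object@lambda,
              if (length(object@active_set))
                paste(object@active_set, collapse = ", ") else "(none)"))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult [%s] outcome=%s, %d splits\n", object@model_type,
              object@outcome_name, object@n_splits))
  if (length(object@lambda_grid))
    cat(sprintf("  lambda_min=%.4g  MSE_test=%.4g  MSE_all=%.4g\n",
                object@lambda_min,
                object@mse_test_mean[which.min(abs(object@lambda_grid -
                                                   object@lambda_min))],
                object@mse_all))
  else
    cat(sprintf("  MSE_test=%.4g  MSE_all=%.4g\n",
                object@mse_test_mean[1], object@mse_all))
})

setMethod("show", "EstimatorMap", function(object) {
  cat(sprintf("EstimatorMap over %d voxels; |v| range [%.3g, %.3g]\n",
              length(object@v), min(object@v), max(object@v)))
})
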