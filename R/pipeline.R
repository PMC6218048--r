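#' Assemble a run configuration
#'
#' A run is fully reproducible from its configuration and seed. Input data
#' come either from a fixture directory (\code{input_dir}, as written by
#' \code{\link{writeFixture}}) or from an in-config phantom specification
#' (\code{phantom}). The default CV profile is the reduced desk-scale one
#' (100 splits); the full protocol (500 splits, 0.3 holdout, 100 penalty
#' steps, J = 5) is selected by setting \code{n_splits = 500}.
#'
#' @param input_dir fixture directory, or NULL to generate a phantom.
#' @param phantom list(grid_shape, kinds, roi_label, spec) describing the
#'   phantom (spec a \code{\link{cohortSpec}}); ignored when
#'   \code{input_dir} is given.
#' @param output_dir where reports are written.
#' @param rois integer ROI labels to analyze.
#' @param sides sides to analyze.
#' @param models list of model rows: list(outcome, side, roi, covariates).
#' @param subgroups subgroup presets for the pattern analysis (possibly
#'   empty).
#' @param n_splits,holdout_fraction,steps,J,top_k CV and reporting
#'   settings.
#' @param seed master seed.
#' @return list of class "RunConfig".
#' @export
runConfig <- function(input_dir = NULL, phantom = NULL,
                      output_dir = tempfile("pclasso_run"),
                      rois = c(1L, 2L), sides = c("better", "worse"),
                      models = list(
                        list(outcome = "aDD", side = "better", roi = 1L),
                        list(outcome = "aDD", side = "worse", roi = 1L),
                        list(outcome = "LMS_better", side = "better",
                             roi = 1L),
                        list(outcome = "LMS_worse", side = "worse",
                             roi = 1L)),
                      subgroups = list(), n_splits = 100L,
                      holdout_fraction = 0.3, steps = 100L, J = 5L,
                      top_k = 5L, seed = 1L) {
  if (is.null(input_dir) && is.null(phantom))
    phantom <- list()
  structure(list(input_dir = input_dir, phantom = phantom,
                 output_dir = output_dir, rois = as.integer(rois),
                 sides = sides, models = models, subgroups = subgroups,
                 n_splits = as.integer(n_splits),
                 holdout_fraction = holdout_fraction,
                 steps = as.integer(steps), J = as.integer(J),
                 top_k = as.integer(top_k), seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose fields mirror \code{\link{runConfig}}
#'   arguments.
#' @return a RunConfig.
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!is.null(raw$phantom$spec))
    raw$phantom$spec <- do.call(cohortSpec, raw$phantom$spec)
  do.call(runConfig, raw)
}

# Materialize the dataset a config describes.
.loadDataset <- function(config) {
  if (!is.null(config$input_dir)) {
    fx <- readFixture(config$input_dir)
    return(list(template = fx$template, clinical = fx$clinical,
                images = fx$images, basis = NULL))
  }
  ph <- config$phantom
  template <- do.call(makeTemplate, ph[intersect(names(ph),
                                                 c("grid_shape",
                                                   "roi_geometry"))])
  spec <- ph$spec %||% cohortSpec(seed = config$seed)
  basis <- makePlantedBasis(template, roi_label = ph$roi_label %||% 1L,
                            kinds = ph$kinds %||%
                              c("global_positive", "ap_gradient",
                                "is_gradient"),
                            mean_level = spec$mean_level)
  cohort <- sampleCohort(spec, basis)
  images <- renderImages(template, basis, cohort$scores,
                         noise_sigma = spec$noise_sigma,
                         seed = spec$seed + 1L)
  list(template = template, clinical = cohort$clinical, images = images,
       basis = basis, cohort = cohort)
}

.ensureDir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Pattern-discovery analysis
#'
#' Runs voxel-wise PCA per ROI and side (and per subgroup when requested),
#' writing VAF and score tables, per-PC loading volumes, MIP matrices, and
#' cross-side / cross-subgroup loading-similarity matrices.
#'
#' @param config a \code{\link{runConfig}}.
#' @return invisibly, a nested list of \linkS4class{PCDecomposition}s and
#'   similarity matrices.
#' @export
runPatternAnalysis <- function(config) {
  ds <- .loadDataset(config)
  out <- .ensureDir(config$output_dir)
  report <- list()
  for (roi in config$rois) {
    pcds <- list()
    for (side in config$sides) {
      vm <- extractVoxelMatrix(ds$images[[side]], ds$template, roi)
      pcd <- fitPCA(vm)
      pcds[[side]] <- pcd
      tag <- sprintf("roi%d_%s", roi, side)
      utils::write.csv(data.frame(pc = seq_along(vaf(pcd)),
                                  vaf_percent = vaf(pcd)),
                       file.path(out, paste0("vaf_", tag, ".csv")),
                       row.names = FALSE)
      utils::write.csv(data.frame(subject_id = pcd@subject_ids,
                                  patternScores(pcd)),
                       file.path(out, paste0("scores_", tag, ".csv")),
                       row.names = FALSE)
      for (k in seq_len(min(config$top_k, nrow(patternLoadings(pcd))))) {
        vol <- embedVoxels(patternLoadings(pcd)[k, ], voxelIndex(pcd),
                           dim(ds$template@labels))
        writeParametricImage(
          methods::new("ParametricImage", values = vol,
                       affine = diag(c(ds$template@voxel_size, 1)),
                       voxel_size = ds$template@voxel_size,
                       kind = "weights"),
          file.path(out, sprintf("loading_%s_PC%d.nii.gz", tag, k)))
        mip <- mipRender(patternLoadings(pcd)[k, ], "AP",
                         grid_shape = dim(ds$template@labels),
                         voxel_index = voxelIndex(pcd))
        utils::write.csv(mip$positive,
                         file.path(out, sprintf("mip_%s_PC%d_pos.csv",
                                                tag, k)), row.names = FALSE)
        utils::write.csv(mip$negative,
                         file.path(out, sprintf("mip_%s_PC%d_neg.csv",
                                                tag, k)), row.names = FALSE)
      }
    }
    if (all(c("better", "worse") %in% names(pcds))) {
      sim <- compareLoadings(pcds$better, pcds$worse, config$top_k)
      utils::write.csv(sim,
                       file.path(out, sprintf("similarity_roi%d_sides.csv",
                                              roi)), row.names = FALSE)
      report[[as.character(roi)]]$side_similarity <- sim
    }
    if (length(config$subgroups)) {
      vm <- extractVoxelMatrix(ds$images[[config$sides[1]]], ds$template,
                               roi)
      sgs <- runSubgroupPCA(vm, ds$clinical, config$subgroups)
      nm <- names(sgs)
      for (a in seq_along(sgs)) for (b in seq_along(sgs)) if (a < b) {
        sim <- compareLoadings(sgs[[a]], sgs[[b]], config$top_k)
        utils::write.csv(sim,
          file.path(out, sprintf("similarity_roi%d_%s_vs_%s.csv", roi,
                                 nm[a], nm[b])), row.names = FALSE)
      }
      report[[as.character(roi)]]$subgroups <- sgs
    }
    report[[as.character(roi)]]$decompositions <- pcds
  }
  invisible(report)
}

.outcomeVector <- function(clinical, outcome) {
  if (!outcome %in% names(clinical))
    stopf("outcome column '%s' missing from the clinical table", outcome,
          class = "pclasso_validation_error")
  clinical[[outcome]]
}

#' Prediction analysis: PC-LASSO versus reference models
#'
#' For every configured model row, fits the constant, mean-BR and PC-LASSO
#' models on a shared split sequence and writes the comparison table,
#' trace-plot data, predicted-versus-actual data, coefficient statistics
#' and the voxel-space estimator map with its MIPs.
#'
#' @param config a \code{\link{runConfig}}.
#' @return invisibly, list(table = comparison data.frame, fits = per-row
#'   results).
#' @export
runPrediction <- function(config) {
  ds <- .loadDataset(config)
  out <- .ensureDir(config$output_dir)
  rows <- list()
  fits <- list()
  for (m in config$models) {
    vm <- extractVoxelMatrix(ds$images[[m$side]], ds$template, m$roi)
    ord <- match(ds$clinical$subject_id, vm@subject_ids)
    vmData <- vm@data[ord, , drop = FALSE]
    pcd <- fitPCA(vm)
    J <- min(config$J, ncol(patternScores(pcd)))
    design <- patternScores(pcd)[ord, seq_len(J), drop = FALSE]
    for (cv in (m$covariates %||% character()))
      design <- cbind(design,
                      stats::setNames(data.frame(ds$clinical[[cv]]), cv))
    design <- as.matrix(design)
    y <- .outcomeVector(ds$clinical, m$outcome)
    splits <- makeSplits(length(y), config$n_splits,
                         config$holdout_fraction, config$seed)
    pcl <- repeatedHoldoutCV(design, y, steps = config$steps,
                             splits = splits, outcome_name = m$outcome)
    refs <- fitReferenceModels(rowMeans(vmData), y, splits,
                               outcome_name = m$outcome)
    tag <- sprintf("%s_%s_roi%d", m$outcome, m$side, m$roi)
    utils::write.csv(traceData(pcl, design, y),
                     file.path(out, paste0("trace_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(predictedVsActual(pcl, design, y),
                     file.path(out, paste0("pva_pclasso_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(predictedVsActual(refs$mean_br, rowMeans(vmData), y),
                     file.path(out, paste0("pva_meanbr_", tag, ".csv")),
                     row.names = FALSE)
    cstat <- data.frame(input = names(pcl@coef_mean),
                        coef_mean = pcl@coef_mean, coef_sd = pcl@coef_sd,
                        p_value = pcl@p_values[names(pcl@coef_mean)])
    utils::write.csv(cstat, file.path(out, paste0("coef_", tag, ".csv")),
                     row.names = FALSE)
    est <- computeEstimator(pcd, pcl@full_model)
    writeEstimatorMap(est, ds$template, file.path(out, paste0("est_", tag)))
    for (ax in c("LM", "AP", "IS")) {
      mip <- mipRender(est, ax, grid_shape = dim(ds$template@labels))
      utils::write.csv(mip$positive,
                       file.path(out, sprintf("mip_est_%s_%s_pos.csv", tag,
                                              ax)), row.names = FALSE)
      utils::write.csv(mip$negative,
                       file.path(out, sprintf("mip_est_%s_%s_neg.csv", tag,
                                              ax)), row.names = FALSE)
    }
    rows[[tag]] <- list(outcome = m$outcome, side = m$side,
                        constant = refs$constant, mean_br = refs$mean_br,
                        pclasso = pcl)
    fits[[tag]] <- list(pclasso = pcl, refs = refs, estimator = est,
                        decomposition = pcd)
  }
  tab <- cvSummaryTable(rows)
  utils::write.csv(tab, file.path(out, "model_comparison.csv"),
                   row.names = FALSE)
  invisible(list(table = tab, fits = fits))
}

#' End-to-end phantom demonstration
#'
#' Generates a phantom fixture, runs the pattern and prediction analyses on
#' it, and writes a summary with planted-versus-recovered pattern
#' similarities and the selection outcome of each model.
#'
#' @param config a \code{\link{runConfig}} with a phantom specification.
#' @return invisibly, the summary list.
#' @export
runPhantomDemo <- function(config) {
  ds <- .loadDataset(config)
  out <- .ensureDir(config$output_dir)
  fixdir <- file.path(out, "fixture")
  writeFixture(ds$cohort, ds$images, fixdir, ds$template)
  patterns <- runPatternAnalysis(config)
  prediction <- runPrediction(config)
  roi <- config$phantom$roi_label %||% 1L
  pcd <- patterns[[as.character(roi)]]$decompositions[[config$sides[1]]]
  sim <- compareLoadings(pcd, ds$basis,
                         top_k = nrow(patternLoadings(ds$basis)))
  recovery <- apply(sim[seq_len(min(nrow(sim),
                                    nrow(patternLoadings(ds$basis)))), ,
                        drop = FALSE], 2, max)
  summary <- list(seed = config$seed,
                  planted_recovery_abs_cosine = as.list(
                    stats::setNames(recovery,
                                    paste0("pattern", seq_along(recovery)))),
                  retained_terms = lapply(prediction$fits, function(f)
                    f$pclasso@retained_terms),
                  comparison = "model_comparison.csv")
  jsonlite::write_json(summary, file.path(out, "phantom_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
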