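#' Build a synthetic striatal template
#'
#' Constructs a common-space labeled template with two disjoint axis-aligned
#' ellipsoidal ROIs: the putamen (label 1), elongated along the
#' anteroposterior axis, and the caudate + ventral striatum (label 2),
#' elongated along the inferosuperior axis. Deterministic for fixed inputs.
#'
#' @param grid_shape integer(3), each >= 8. Default 32 x 48 x 32
#'   (LM x AP x IS).
#' @param roi_geometry list with elements \code{putamen} and \code{caudate},
#'   each a list(center, radii) in 0-based voxel coordinates.
#' @param voxel_size mm per axis.
#' @return a \linkS4class{LabeledTemplate}.
#' @export
makeTemplate <- function(grid_shape = c(32L, 48L, 32L),
                         roi_geometry = list(
                           putamen = list(center = c(10, 24, 16),
                                          radii = c(5, 14, 6)),
                           caudate = list(center = c(22, 30, 18),
                                          radii = c(4, 6, 10))),
                         voxel_size = c(2, 2, 2)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stopf("grid_shape must be 3 integers, each >= 8",
          class = "pclasso_config_error")
  for (roi in c("putamen", "caudate")) {
    g <- roi_geometry[[roi]]
    if (is.null(g) || length(g$center) != 3 || length(g$radii) != 3 ||
        any(g$radii <= 0))
      stopf("roi_geometry$%s must provide center and positive radii", roi,
            class = "pclasso_config_error")
    if (any(g$center - g$radii < 0) ||
        any(g$center + g$radii > grid_shape - 1))
      stopf("%s ellipsoid extends outside the grid", roi,
            class = "pclasso_config_error")
  }
  if (all(roi_geometry$putamen$center == roi_geometry$caudate$center))
    stopf("putamen and caudate centers coincide",
          class = "pclasso_config_error")

  ii <- seq_len(grid_shape[1]) - 1
  jj <- seq_len(grid_shape[2]) - 1
  kk <- seq_len(grid_shape[3]) - 1
  insideEllipsoid <- function(g) {
    di <- ((ii - g$center[1]) / g$radii[1])^2
    dj <- ((jj - g$center[2]) / g$radii[2])^2
    dk <- ((kk - g$center[3]) / g$radii[3])^2
    outer(outer(di, dj, `+`), dk, `+`) <= 1
  }
  put <- insideEllipsoid(roi_geometry$putamen)
  cau <- insideEllipsoid(roi_geometry$caudate)
  if (any(put & cau))
    stopf("putamen and caudate ellipsoids overlap",
          class = "pclasso_config_error")
  labels <- array(0L, grid_shape)
  labels[put] <- 1L
  labels[cau] <- 2L
  methods::new("LabeledTemplate", labels = labels,
               voxel_size = as.numeric(voxel_size),
               geometry = roi_geometry)
}

.rawPattern <- function(kind, vidx, pos) {
  switch(kind,
    global_positive = rep(1, nrow(vidx)),
    ap_gradient = vidx[, 2] - mean(vidx[, 2]),
    is_gradient = vidx[, 3] - mean(vidx[, 3]),
    # ventromedial-to-dorsolateral: diagonal over the IS and LM indices
    vd_gradient = {
      r <- vidx[, 3] + vidx[, 1]
      r - mean(r)
    },
    noise_pattern = withSeed(982451653L + pos, stats::rnorm(nrow(vidx))),
    stopf("unknown pattern kind '%s'", kind, class = "pclasso_config_error"))
}

#' Build an orthonormal planted pattern basis over one ROI
#'
#' Raw patterns (a constant all-positive pattern; mean-centered linear ramps
#' along named anatomical axes; deterministic pseudo-random patterns) are
#' orthonormalized sequentially in the given order, global pattern first, so
#' that the global pattern keeps all-nonnegative weights.
#'
#' @param template a \linkS4class{LabeledTemplate}.
#' @param roi_label ROI to span (default 1 = putamen).
#' @param kinds character vector of pattern tags among global_positive,
#'   ap_gradient, is_gradient, vd_gradient, noise_pattern.
#' @param mean_level baseline BR added by the renderer (dimensionless).
#' @return a \linkS4class{PlantedBasis}.
#' @export
makePlantedBasis <- function(template, roi_label = 1L,
                             kinds = c("global_positive", "ap_gradient",
                                       "is_gradient"),
                             mean_level = 2) {
  if (length(kinds) < 1) stopf("at least one pattern kind required",
                               class = "pclasso_config_error")
  vidx <- roiVoxelIndex(template, roi_label)
  V <- nrow(vidx)
  P <- matrix(0, length(kinds), V)
  for (m in seq_along(kinds)) {
    p <- .rawPattern(kinds[m], vidx, m)
    if (m > 1) p <- p - drop(P[1:(m - 1), , drop = FALSE] %*% p) %*%
        P[1:(m - 1), , drop = FALSE]  # sequential Gram-Schmidt
    p <- drop(p)
    nrm <- sqrt(sum(p^2))
    if (nrm < 1e-10)
      stopf("pattern %d (%s) is degenerate after orthogonalization", m,
            kinds[m], class = "pclasso_config_error")
    P[m, ] <- p / nrm
  }
  methods::new("PlantedBasis", patterns = P, kinds = kinds,
               mean_level = mean_level, roi_label = as.integer(roi_label),
               voxel_index = vidx, grid_shape = dim(template@labels))
}

#' Specification of a synthetic cohort
#'
#' Defines the generative model of a phantom cohort: disease durations are
#' uniform on \code{dd_range}; aDD follows from \code{\link{computeADD}};
#' per-pattern scores are linear in aDD with Gaussian noise; the lateral
#' motor score is linear in selected pattern scores; worse-side pattern
#' scores receive an additive offset (recycled per pattern), emulating the
#' worse hemisphere as a more progressed version of the better one.
#'
#' Defaults emulate the modeled cohort: 40 subjects, DD spanning 0-16
#' years, pattern 1 (global binding) declining with aDD, patterns 2-3
#' varying independently, LMS driven by patterns 1 and 3.
#'
#' @param n_subjects integer >= 2.
#' @param dd_range nonnegative ordered range of disease duration (years).
#' @param score_model data.frame with columns intercept, slope, sd: one row
#'   per planted pattern; scores = intercept + slope * aDD + N(0, sd).
#' @param lms_model list(intercept, coefficients, sd): LMS = intercept +
#'   coefficients . scores + N(0, sd), clamped to [0, 28].
#' @param asymmetry_offset numeric, additive worse-side score shift
#'   (recycled to the number of patterns).
#' @param noise_sigma voxel noise SD in BR units, >= 0.
#' @param mean_level baseline BR.
#' @param seed integer master seed.
#' @param add_params \code{\link{addParams}} for the aDD map.
#' @return list of class "CohortSpec".
#' @export
cohortSpec <- function(n_subjects = 40L,
                       dd_range = c(0, 16),
                       score_model = data.frame(
                         intercept = c(12, 0, 0),
                         slope = c(-1.5, 0, 0),
                         sd = c(1, 3, 2)),
                       lms_model = list(intercept = 6,
                                        coefficients = c(-0.5, 0, 1.2),
                                        sd = 0.4),
                       asymmetry_offset = c(-2, 0, 0),
                       noise_sigma = 0.1,
                       mean_level = 2,
                       seed = 1L,
                       add_params = addParams()) {
  if (n_subjects < 2) stopf("n_subjects must be >= 2",
                            class = "pclasso_config_error")
  if (length(dd_range) != 2 || any(dd_range < 0) ||
      dd_range[2] < dd_range[1])
    stopf("dd_range must be nonnegative and ordered",
          class = "pclasso_config_error")
  if (any(score_model$sd < 0) || lms_model$sd < 0 || noise_sigma < 0)
    stopf("noise SDs must be >= 0", class = "pclasso_config_error")
  structure(list(n_subjects = as.integer(n_subjects), dd_range = dd_range,
                 score_model = score_model, lms_model = lms_model,
                 asymmetry_offset = asymmetry_offset,
                 noise_sigma = noise_sigma, mean_level = mean_level,
                 seed = as.integer(seed), add_params = add_params),
            class = "CohortSpec")
}

# distribute an integer LMS total over the 7 items, each capped at 4
.lmsToItems <- function(total) {
  total <- max(0L, min(28L, as.integer(round(total))))
  base <- total %/% 7L
  rem <- total %% 7L
  items <- rep(base, 7L) + c(rep(1L, rem), rep(0L, 7L - rem))
  stats::setNames(pmin(items, 4L), lmsItems)
}

#' Sample a synthetic clinical cohort
#'
#' Draws disease durations, pattern scores and lateralized motor scores
#' according to a \code{\link{cohortSpec}}; fully reproducible from the
#' spec's seed.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param basis a \linkS4class{PlantedBasis}; the score model must have one
#'   row per basis pattern.
#' @return list(clinical = data.frame, scores = list(better, worse)
#'   N x K score matrices, spec = spec).
#' @export
sampleCohort <- function(spec, basis) {
  stopifnot(inherits(spec, "CohortSpec"), methods::is(basis, "PlantedBasis"))
  K <- nrow(basis@patterns)
  if (nrow(spec$score_model) != K)
    stopf("score_model has %d rows but the basis has %d patterns",
          nrow(spec$score_model), K, class = "pclasso_config_error")
  n <- spec$n_subjects
  withSeed(spec$seed, {
    DD <- stats::runif(n, spec$dd_range[1], spec$dd_range[2])
    aDD <- computeADD(DD, spec$add_params)
    Sb <- sapply(seq_len(K), function(k)
      spec$score_model$intercept[k] + spec$score_model$slope[k] * aDD +
        stats::rnorm(n, 0, spec$score_model$sd[k]))
    Sb <- matrix(Sb, n, K)
    off <- rep_len(spec$asymmetry_offset, K)
    Sw <- sweep(Sb, 2, -off)  # worse side = shifted better-side scores
    lmsOf <- function(S)
      pmin(28, pmax(0, spec$lms_model$intercept +
                      drop(S %*% rep_len(spec$lms_model$coefficients, K)) +
                      stats::rnorm(n, 0, spec$lms_model$sd)))
    LMSb <- lmsOf(Sb)
    LMSw <- lmsOf(Sw)
    worse_body <- sample(c("left", "right"), n, replace = TRUE)
    age <- round(pmin(85, pmax(35, stats::rnorm(n, 61, 9))))
    agonist <- sample(c("OFF", "ON"), n, replace = TRUE)
    agled <- ifelse(agonist == "ON",
                    round(pmax(25, stats::rnorm(n, 160, 90))), 0)
    sex <- sample(c("M", "F"), n, replace = TRUE)

    ids <- sprintf("S%03d", seq_len(n))
    itemsW <- t(vapply(LMSw, .lmsToItems, numeric(7)))
    itemsB <- t(vapply(LMSb, .lmsToItems, numeric(7)))
    wl <- worse_body == "left"
    itemsLeft <- itemsB; itemsLeft[wl, ] <- itemsW[wl, ]
    itemsRight <- itemsW; itemsRight[wl, ] <- itemsB[wl, ]
    colnames(itemsLeft) <- .sideItemCols("left")
    colnames(itemsRight) <- .sideItemCols("right")

    clinical <- data.frame(subject_id = ids, group = "PD", DD = DD,
                           aDD = aDD, LMS_better = LMSb, LMS_worse = LMSw,
                           worse_body_side = worse_body, age = age,
                           AgLED = agled, agonist_status = agonist,
                           sex = sex, stringsAsFactors = FALSE)
    clinical <- cbind(clinical, itemsLeft, itemsRight)
    rownames(Sb) <- rownames(Sw) <- ids
    colnames(Sb) <- colnames(Sw) <- paste0("pattern", seq_len(K))
    list(clinical = clinical, scores = list(better = Sb, worse = Sw),
         spec = spec)
  })
}

.renderOne <- function(template, basis, s, noise_sigma, id, side) {
  vals <- array(0, dim(template@labels))
  vidx <- basis@voxel_index
  lin <- 1L + vidx[, 1] + dim(vals)[1] * (vidx[, 2] + dim(vals)[2] * vidx[, 3])
  roi <- basis@mean_level + drop(s %*% basis@patterns)
  if (noise_sigma > 0) roi <- roi + stats::rnorm(length(roi), 0, noise_sigma)
  vals[lin] <- pmax(roi, 0)
  methods::new("ParametricImage", values = vals,
               affine = diag(c(template@voxel_size, 1)),
               voxel_size = template@voxel_size, subject_id = id,
               side = side, kind = "BR")
}

#' Render phantom BR images from planted scores
#'
#' Voxel values inside the ROI are mean_level + sum_k s_nk * omega_k plus
#' iid Gaussian voxel noise, clipped at zero; voxels outside the ROI are 0.
#'
#' @param template a \linkS4class{LabeledTemplate}.
#' @param basis a \linkS4class{PlantedBasis}.
#' @param true_scores an N x K score matrix (one side) or a
#'   list(better = , worse = ) of score matrices.
#' @param noise_sigma voxel noise SD (BR units).
#' @param seed integer seed for the voxel noise.
#' @param subject_ids optional ids (default from score row names).
#' @param side side tag used when true_scores is a single matrix.
#' @return a list of \linkS4class{ParametricImage}s, or a
#'   list(better = , worse = ) of such lists.
#' @export
renderImages <- function(template, basis, true_scores, noise_sigma = 0,
                         seed = 1L, subject_ids = NULL, side = "better") {
  if (is.list(true_scores) && !is.matrix(true_scores)) {
    seeds <- childSeeds(seed, length(true_scores))
    return(stats::setNames(lapply(seq_along(true_scores), function(i)
      renderImages(template, basis, true_scores[[i]], noise_sigma,
                   seeds[i], subject_ids, names(true_scores)[i])),
      names(true_scores)))
  }
  S <- as.matrix(true_scores)
  if (ncol(S) != nrow(basis@patterns))
    stopf("score matrix has %d columns but the basis has %d patterns",
          ncol(S), nrow(basis@patterns), class = "pclasso_shape_error")
  ids <- subject_ids %||% rownames(S) %||% sprintf("S%03d", seq_len(nrow(S)))
  withSeed(seed,
    lapply(seq_len(nrow(S)), function(n)
      .renderOne(template, basis, S[n, ], noise_sigma, ids[n], side)))
}

#' Write a phantom fixture to disk
#'
#' Writes one NIfTI-1 image per subject and side
#' (\code{sub-<id>_<side>.nii.gz}), the template label map, the clinical
#' table as CSV, and a JSON manifest recording the generating seed and
#' cohort specification. The fixture round-trips losslessly through
#' \code{\link{readFixture}}.
#'
#' @param cohort result of \code{\link{sampleCohort}}.
#' @param images result of \code{\link{renderImages}} (list or per-side
#'   list).
#' @param directory output directory (created if needed).
#' @param template the \linkS4class{LabeledTemplate}.
#' @return the manifest (list), invisibly.
#' @export
writeFixture <- function(cohort, images, directory, template) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok || file.access(directory, 2) != 0)
    stopf("directory not writable: %s", directory,
          class = "pclasso_io_error")
  if (!is.null(names(images)) && !methods::is(images[[1]], "ParametricImage"))
    flat <- unlist(images, recursive = FALSE)
  else flat <- images
  files <- character()
  for (im in flat) {
    f <- sprintf("sub-%s_%s.nii.gz", im@subject_id, im@side)
    writeParametricImage(im, file.path(directory, f))
    files <- c(files, f)
  }
  writeTemplate(template, file.path(directory, "template.nii.gz"))
  utils::write.csv(cohort$clinical, file.path(directory, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(subject_id = rownames(cohort$scores$better),
               side = rep(names(cohort$scores),
                          each = nrow(cohort$scores$better)),
               rbind(cohort$scores$better, cohort$scores$worse)),
    file.path(directory, "true_scores.csv"), row.names = FALSE)
  manifest <- list(seed = cohort$spec$seed,
                   n_subjects = cohort$spec$n_subjects,
                   spec = unclass(cohort$spec[setdiff(names(cohort$spec),
                                                      "add_params")]),
                   add_params = unclass(cohort$spec$add_params),
                   images = files, template = "template.nii.gz",
                   clinical = "clinical.csv")
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a phantom fixture written by \code{\link{writeFixture}}
#'
#' @param directory fixture directory.
#' @return list(manifest, template, clinical, images) where images is a
#'   list keyed by side of \linkS4class{ParametricImage} lists.
#' @export
readFixture <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) stopf("no manifest.json in %s", directory,
                              class = "pclasso_io_error")
  manifest <- jsonlite::fromJSON(mf, simplifyVector = TRUE)
  template <- readTemplate(file.path(directory, manifest$template))
  clinical <- readClinicalTable(file.path(directory, manifest$clinical))
  parse <- regmatches(manifest$images,
                      regexec("^sub-(.+)_([a-z]+)\\.nii(\\.gz)?$",
                              manifest$images))
  images <- list()
  for (m in seq_along(manifest$images)) {
    id <- parse[[m]][2]; side <- parse[[m]][3]
    img <- readParametricImage(file.path(directory, manifest$images[m]),
                               subject_id = id, side = side)
    images[[side]] <- c(images[[side]], list(img))
  }
  list(manifest = manifest, template = template, clinical = clinical,
       images = images)
}
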