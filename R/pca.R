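#' Voxel-wise PCA of a subject-by-voxel BR matrix
#'
#' Removes the per-voxel mean (no variance scaling: voxels are commensurate
#' BR values and the first component should represent a weighted mean) and
#' decomposes the centered matrix by SVD. Components are ranked by variance
#' accounted for (VAF, percent of total centered variance); K =
#' min(N - 1, V); loadings are sign-canonicalized so each loading's weight
#' sum is nonnegative.
#'
#' @param voxel_matrix a \linkS4class{VoxelMatrix} (N >= 2 subjects).
#' @return a \linkS4class{PCDecomposition}; mean_vector + scores %*%
#'   loadings reconstructs the input at full rank.
#' @export
fitPCA <- function(voxel_matrix) {
  stopifnot(methods::is(voxel_matrix, "VoxelMatrix"))
  X <- voxel_matrix@data
  if (nrow(X) < 2) stopf("PCA requires at least 2 subjects")
  assertFinite(X, "voxel matrix")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  tot <- sum(Xc^2)
  if (tot < 1e-24)
    stopf("voxel matrix is constant across subjects (zero variance)",
          class = "pclasso_degenerate_error")
  K <- min(nrow(X) - 1L, ncol(X))
  sv <- svd(Xc, nu = K, nv = K)
  loadings <- t(sv$v)
  scores <- sv$u %*% diag(sv$d[seq_len(K)], K, K)
  vafv <- 100 * sv$d[seq_len(K)]^2 / tot
  dimnames(loadings) <- list(paste0("PC", seq_len(K)), NULL)
  dimnames(scores) <- list(voxel_matrix@subject_ids, paste0("PC", seq_len(K)))
  pcd <- methods::new("PCDecomposition", mean_vector = mu,
                      loadings = loadings, scores = scores, vaf = vafv,
                      voxel_index = voxel_matrix@voxel_index,
                      side = voxel_matrix@side,
                      roi_label = voxel_matrix@roi_label,
                      subject_ids = voxel_matrix@subject_ids)
  canonicalSign(pcd)
}

#' Canonicalize PC loading signs
#'
#' PCA does not determine loading signs. Each loading (with its score
#' column) is flipped so that its weight sum is nonnegative; for an exactly
#' zero-sum loading the largest-magnitude weight is made positive. The
#' reconstruction is unchanged.
#'
#' @param decomposition a \linkS4class{PCDecomposition}.
#' @return the decomposition with canonical signs.
#' @export
canonicalSign <- function(decomposition) {
  L <- decomposition@loadings
  S <- decomposition@scores
  for (k in seq_len(nrow(L))) {
    s <- sum(L[k, ])
    flip <- if (abs(s) > 1e-8) s < 0 else L[k, which.max(abs(L[k, ]))] < 0
    if (flip) {
      L[k, ] <- -L[k, ]
      S[, k] <- -S[, k]
    }
  }
  decomposition@loadings <- L
  decomposition@scores <- S
  decomposition
}

#' Project voxel data onto fitted loadings
#'
#' scores = (data - mean_vector) %*% t(loadings); projecting the training
#' matrix reproduces the stored scores.
#'
#' @param decomposition a \linkS4class{PCDecomposition}.
#' @param voxel_matrix a \linkS4class{VoxelMatrix} (or bare matrix with
#'   matching columns) over the same voxel index.
#' @return N x K score matrix.
#' @export
projectScores <- function(decomposition, voxel_matrix) {
  if (methods::is(voxel_matrix, "VoxelMatrix")) {
    if (!identical(voxel_matrix@voxel_index, decomposition@voxel_index))
      stopf("voxel index mismatch between matrix and decomposition",
            class = "pclasso_validation_error")
    X <- voxel_matrix@data
  } else X <- rbind(voxel_matrix)
  if (ncol(X) != length(decomposition@mean_vector))
    stopf("voxel count mismatch", class = "pclasso_validation_error")
  sweep(X, 2, decomposition@mean_vector) %*% t(decomposition@loadings)
}

#' Compare loadings between two decompositions
#'
#' Entry (a, b) is |cosine| between loading a of the first and loading b of
#' the second decomposition; sign-invariant by construction.
#'
#' @param decompA,decompB \linkS4class{PCDecomposition}s (or
#'   \linkS4class{PlantedBasis}) over the same voxel index.
#' @param top_k number of leading loadings compared from each (default 5).
#' @return top_k x top_k similarity matrix in [0, 1].
#' @export
compareLoadings <- function(decompA, decompB, top_k = 5L) {
  if (!identical(voxelIndex(decompA), voxelIndex(decompB)))
    stopf("voxel index mismatch between decompositions",
          class = "pclasso_validation_error")
  A <- patternLoadings(decompA)
  B <- patternLoadings(decompB)
  ka <- min(top_k, nrow(A)); kb <- min(top_k, nrow(B))
  A <- A[seq_len(ka), , drop = FALSE]
  B <- B[seq_len(kb), , drop = FALSE]
  A <- A / sqrt(rowSums(A^2))
  B <- B / sqrt(rowSums(B^2))
  abs(tcrossprod(A, B))
}

#' Subgroup presets for stage-stratified PCA
#'
#' Mirrors the stage sub-groups used for pattern-consistency analysis:
#' \itemize{
#'   \item "mixed_hc_early": HC plus PD with DD <= 2 years;
#'   \item "early_pd": PD with DD <= 3 years;
#'   \item "moderate_pd": PD with DD >= 4 years.
#' }
#'
#' @param name preset name.
#' @param exclude_agonist_on drop agonist-ON subjects (used for the
#'   postsynaptic tracer, whose binding is affected by chronic agonist
#'   treatment).
#' @return list(name, groups, dd_min, dd_max, exclude_agonist_on).
#' @export
subgroupPreset <- function(name = c("mixed_hc_early", "early_pd",
                                    "moderate_pd"),
                           exclude_agonist_on = FALSE) {
  name <- match.arg(name)
  spec <- switch(name,
    mixed_hc_early = list(groups = c("HC", "PD"), dd_min = -Inf, dd_max = 2),
    early_pd = list(groups = "PD", dd_min = -Inf, dd_max = 3),
    moderate_pd = list(groups = "PD", dd_min = 4, dd_max = Inf))
  c(list(name = name), spec, list(exclude_agonist_on = exclude_agonist_on))
}

.selectSubgroup <- function(clinical, sg) {
  sel <- clinical$group %in% sg$groups &
    (clinical$group != "PD" |
       (clinical$DD >= sg$dd_min & clinical$DD <= sg$dd_max))
  if (isTRUE(sg$exclude_agonist_on) && !is.null(clinical$agonist_status))
    sel <- sel & clinical$agonist_status != "ON"
  clinical$subject_id[sel]
}

#' Stage-stratified PCA
#'
#' Runs \code{\link{fitPCA}} on the rows of a voxel matrix selected by each
#' subgroup filter, recording the filter and subject count as provenance.
#'
#' @param voxel_matrix a \linkS4class{VoxelMatrix}.
#' @param clinical_table a clinical data.frame with subject_id, group, DD
#'   (and optionally agonist_status).
#' @param subgroups list of \code{\link{subgroupPreset}}-style filters (or
#'   preset names).
#' @return named list of \linkS4class{PCDecomposition}s.
#' @export
runSubgroupPCA <- function(voxel_matrix, clinical_table,
                           subgroups = list("mixed_hc_early", "early_pd",
                                            "moderate_pd")) {
  out <- list()
  for (sg in subgroups) {
    if (is.character(sg)) sg <- subgroupPreset(sg)
    ids <- .selectSubgroup(clinical_table, sg)
    rows <- which(voxel_matrix@subject_ids %in% ids)
    if (length(rows) < 2)
      stopf("subgroup '%s' selects %d subjects (need >= 2)", sg$name,
            length(rows), class = "pclasso_validation_error")
    sub <- methods::new("VoxelMatrix",
                        data = voxel_matrix@data[rows, , drop = FALSE],
                        voxel_index = voxel_matrix@voxel_index,
                        roi_label = voxel_matrix@roi_label,
                        side = voxel_matrix@side,
                        subject_ids = voxel_matrix@subject_ids[rows])
    pcd <- fitPCA(sub)
    pcd@provenance <- list(subgroup = sg, n = length(rows))
    out[[sg$name]] <- pcd
  }
  out
}
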