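makeVM <- function(X, side = "better", roi = 1L) {
  V <- ncol(X)
  vi <- cbind(i = seq_len(V) - 1L, j = rep(0L, V), k = rep(0L, V))
  new("VoxelMatrix", data = X, voxel_index = vi, roi_label = roi,
      side = side, subject_ids = sprintf("S%03d", seq_len(nrow(X))))
}

test_that("a hand-worked 3x2 example matches the eigendecomposition", {
  X <- rbind(c(2, 0), c(0, 2), c(1, 1))
  pcd <- fitPCA(makeVM(X))
  # PC1 of the 2x2 covariance is (1,-1)/sqrt(2); the zero-sum tie rule
  # makes the first (largest-magnitude) weight positive
  expect_equal(patternLoadings(pcd)[1, ], c(1, -1) / sqrt(2),
               tolerance = 1e-10)
  expect_equal(patternScores(pcd)[, 1], c(sqrt(2), -sqrt(2), 0),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(vaf(pcd)[1], 100, tolerance = 1e-8)
})

test_that("decomposition identities hold: reconstruction, orthonormality, VAF", {
  d <- randomDesign(12, 30, seed = 71)
  X <- d$X + 2
  pcd <- fitPCA(makeVM(X))
  L <- patternLoadings(pcd)
  expect_lt(max(abs(tcrossprod(L) - diag(nrow(L)))), 1e-8)
  recon <- sweep(patternScores(pcd) %*% L, 2, meanVector(pcd), `+`)
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_equal(sum(vaf(pcd)), 100, tolerance = 1e-6)
  expect_true(all(diff(vaf(pcd)) <= 1e-8))
  expect_error(fitPCA(makeVM(matrix(3, 5, 4))),
               class = "pclasso_degenerate_error")
})

test_that("loadings and VAF agree with brute-force covariance eigenanalysis", {
  for (s in 1:5) {
    d <- randomDesign(6, 6, seed = 300 + s)
    pcd <- fitPCA(makeVM(d$X))
    bf <- bruteForcePCA(d$X)
    for (k in seq_len(nrow(bf$loadings))) {
      expect_gt(absCos(patternLoadings(pcd)[k, ], bf$loadings[k, ]),
                1 - 1e-8)
      expect_equal(vaf(pcd)[k], bf$vaf[k], tolerance = 1e-8)
    }
  }
})

test_that("a zero-noise two-pattern cohort has exactly two nonzero VAFs", {
  tc <- tinyCohort(seed = 8L, kinds = c("global_positive", "ap_gradient"))
  imgs <- renderImages(tc$template, tc$basis, tc$cohort$scores$better,
                       noise_sigma = 0, seed = 1L)
  pcd <- fitPCA(extractVoxelMatrix(imgs, tc$template, 1L))
  expect_equal(sum(vaf(pcd) > 1e-8), 2L)
})

test_that("sign canonicalization flips without changing the reconstruction", {
  d <- randomDesign(8, 12, seed = 55)
  pcd <- fitPCA(makeVM(d$X))
  flipped <- pcd
  flipped@loadings <- -flipped@loadings
  flipped@scores <- -flipped@scores
  fixed <- canonicalSign(flipped)
  r1 <- sweep(patternScores(pcd) %*% patternLoadings(pcd), 2,
              meanVector(pcd), `+`)
  r2 <- sweep(patternScores(fixed) %*% patternLoadings(fixed), 2,
              meanVector(fixed), `+`)
  expect_lt(max(abs(r1 - r2)), 1e-12)
  # canonical: every loading already has nonnegative weight sum
  sums <- rowSums(patternLoadings(pcd))
  expect_true(all(sums > -1e-8))
  refixed <- canonicalSign(pcd)                 # all-positive-sum fixed point
  expect_identical(patternLoadings(refixed), patternLoadings(pcd))
})

test_that("projection reproduces training scores and centers correctly", {
  tc <- tinyCohort(seed = 13L)
  imgs <- renderImages(tc$template, tc$basis, tc$cohort$scores$better,
                       noise_sigma = 0, seed = 1L)
  vm <- extractVoxelMatrix(imgs, tc$template, 1L)
  pcd <- fitPCA(vm)
  expect_lt(max(abs(projectScores(pcd, vm) - patternScores(pcd))), 1e-10)
  expect_lt(max(abs(projectScores(pcd, rbind(meanVector(pcd))))), 1e-12)
  # a held-out zero-noise subject projects onto its generating scores
  # (up to the planted-vs-fitted basis rotation, scores reconstruct f)
  hold <- renderImages(tc$template, tc$basis,
                       rbind(c(5, 1, -2)), noise_sigma = 0, seed = 2L)
  f <- extractVoxelMatrix(hold, tc$template, 1L)
  sc <- projectScores(pcd, voxelData(f))
  recon <- meanVector(pcd) + drop(sc %*% patternLoadings(pcd))
  planted <- tc$basis@mean_level +
    drop(c(5, 1, -2) %*% patternLoadings(tc$basis))
  expect_lt(max(abs(recon - planted)), 1e-8)
})

test_that("loading comparison is sign-invariant and detects orthogonality", {
  d <- randomDesign(10, 20, seed = 91)
  pcd <- fitPCA(makeVM(d$X))
  self <- compareLoadings(pcd, pcd, top_k = 4)
  expect_equal(diag(self), rep(1, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(self <= 1 + 1e-12))
  flipped <- pcd
  flipped@loadings <- -flipped@loadings
  expect_equal(compareLoadings(pcd, flipped, top_k = 4), self,
               tolerance = 1e-12)
  expect_lt(max(self[upper.tri(self)]), 1e-6)   # distinct PCs orthogonal
})

test_that("subgroup PCA filters subjects as the stage presets state", {
  # stage-independent patterns: scores iid with well-separated variances,
  # so every stage subgroup sees the same covariance structure
  tpl <- tinyTemplate()
  basis <- makePlantedBasis(tpl)
  spec <- cohortSpec(n_subjects = 120L, seed = 17L,
                     score_model = data.frame(intercept = c(8, 0, 0),
                                              slope = c(0, 0, 0),
                                              sd = c(6, 3, 1.5)),
                     lms_model = list(intercept = 6,
                                      coefficients = c(-0.5, 0, 1.2),
                                      sd = 0.4),
                     asymmetry_offset = c(-2, 0, 0))
  coh <- sampleCohort(spec, basis)
  imgs <- renderImages(tpl, basis, coh$scores$better,
                       noise_sigma = spec$noise_sigma, seed = 3L)
  vm <- extractVoxelMatrix(imgs, tpl, 1L)
  cl <- coh$clinical
  sgs <- runSubgroupPCA(vm, cl)
  expect_named(sgs, c("mixed_hc_early", "early_pd", "moderate_pd"))
  expect_identical(sort(sgs$early_pd@subject_ids),
                   sort(cl$subject_id[cl$DD <= 3]))
  expect_identical(sort(sgs$moderate_pd@subject_ids),
                   sort(cl$subject_id[cl$DD >= 4]))
  # agonist exclusion removes ON subjects
  sgOn <- runSubgroupPCA(vm, cl, list(subgroupPreset("moderate_pd",
                                                     exclude_agonist_on = TRUE)))
  expect_identical(sort(sgOn$moderate_pd@subject_ids),
                   sort(cl$subject_id[cl$DD >= 4 & cl$agonist_status != "ON"]))
  # undersized subgroup is a validation error
  tiny <- cl; tiny$DD <- 0
  expect_error(runSubgroupPCA(vm, tiny, list("moderate_pd")),
               class = "pclasso_validation_error")
  # stage-independent planted patterns: high-VAF loadings agree across stages
  sim <- compareLoadings(sgs$early_pd, sgs$moderate_pd, top_k = 2)
  expect_true(all(diag(sim) >= 0.9))
  expect_true(all(diag(compareLoadings(sgs$early_pd, basis, top_k = 2)) >=
                    0.9))
})
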