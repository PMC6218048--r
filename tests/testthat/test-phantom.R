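test_that("template construction is valid, deterministic and validated", {
  tpl <- makeTemplate()
  lab <- templateLabels(tpl)
  expect_true(sum(lab == 1) > 0 && sum(lab == 2) > 0)
  expect_false(any(lab == 1 & lab == 2))
  expect_identical(lab, templateLabels(makeTemplate()))

  geo <- list(putamen = list(center = c(10, 24, 16), radii = c(5, 14, 6)),
              caudate = list(center = c(10, 24, 16), radii = c(4, 6, 10)))
  expect_error(makeTemplate(roi_geometry = geo),
               class = "pclasso_config_error")
  geo2 <- list(putamen = list(center = c(2, 24, 16), radii = c(5, 14, 6)),
               caudate = list(center = c(22, 30, 18), radii = c(4, 6, 10)))
  expect_error(makeTemplate(roi_geometry = geo2),
               class = "pclasso_config_error")
  expect_error(makeTemplate(grid_shape = c(4, 4, 4)),
               class = "pclasso_config_error")
})

test_that("planted basis is orthonormal with the stated pattern structure", {
  tpl <- tinyTemplate()
  b1 <- makePlantedBasis(tpl, kinds = "global_positive")
  expect_identical(nrow(patternLoadings(b1)), 1L)
  expect_equal(sum(patternLoadings(b1)^2), 1, tolerance = 1e-10)
  expect_true(all(patternLoadings(b1) >= 0))

  b2 <- makePlantedBasis(tpl, kinds = c("global_positive", "ap_gradient"))
  P <- patternLoadings(b2)
  expect_lt(abs(sum(P[1, ] * P[2, ])), 1e-10)

  # the AP ramp increases strictly with the AP index within each (LM, IS)
  # column (orthogonalization against the constant leaves an affine ramp)
  vi <- voxelIndex(b2)
  cols <- split(seq_len(nrow(vi)), paste(vi[, 1], vi[, 3]))
  incr <- vapply(cols, function(ix) {
    ix <- ix[order(vi[ix, 2])]
    length(ix) < 2 || all(diff(P[2, ix]) > 0)
  }, logical(1))
  expect_true(all(incr))

  b5 <- makePlantedBasis(tpl, kinds = c("global_positive", "ap_gradient",
                                        "is_gradient", "vd_gradient",
                                        "noise_pattern"))
  G <- tcrossprod(patternLoadings(b5))
  expect_lt(max(abs(G - diag(5))), 1e-10)
  expect_error(makePlantedBasis(tpl, kinds = "spiral"),
               class = "pclasso_config_error")
})

test_that("cohort sampling follows the generative model and the seed", {
  tpl <- tinyTemplate()
  basis <- makePlantedBasis(tpl, kinds = c("global_positive", "ap_gradient"))
  # zero noise, zero slope: every subject has identical scores
  spec0 <- cohortSpec(n_subjects = 8L,
                      score_model = data.frame(intercept = c(3, 1),
                                               slope = c(0, 0),
                                               sd = c(0, 0)),
                      lms_model = list(intercept = 5, coefficients = c(0, 0),
                                       sd = 0),
                      asymmetry_offset = 0, noise_sigma = 0, seed = 2L)
  coh0 <- sampleCohort(spec0, basis)
  expect_true(all(coh0$scores$better[, 1] == 3))
  expect_true(all(coh0$scores$better[, 2] == 1))
  expect_identical(coh0$scores$better, coh0$scores$worse)

  spec <- cohortSpec(n_subjects = 30L, seed = 9L,
                     score_model = data.frame(intercept = c(3, 1),
                                              slope = c(0.5, 0),
                                              sd = c(0.2, 1)),
                     lms_model = list(intercept = 5,
                                      coefficients = c(0.3, 0), sd = 0.1),
                     asymmetry_offset = c(1, 0))
  b3 <- basis
  cohA <- sampleCohort(spec, b3)
  cohB <- sampleCohort(spec, b3)
  expect_identical(cohA$clinical, cohB$clinical)
  expect_identical(cohA$scores, cohB$scores)
  # worse-side scores are the shifted better-side scores
  expect_equal(cohA$scores$worse[, 1], cohA$scores$better[, 1] + 1)

  # Monte-Carlo check of the linear score generator
  specMC <- cohortSpec(n_subjects = 200L, seed = 3L,
                       score_model = data.frame(intercept = c(10, 0),
                                                slope = c(-1.5, 0),
                                                sd = c(0.05, 1)),
                       lms_model = list(intercept = 5,
                                        coefficients = c(0, 0), sd = 0.1),
                       asymmetry_offset = 0)
  cohMC <- sampleCohort(specMC, basis)
  expect_lt(cor(cohMC$scores$better[, 1], cohMC$clinical$aDD), -0.95)
})

test_that("rendered images realize the planted decomposition", {
  tc <- tinyCohort(seed = 4L)
  tpl <- tc$template; basis <- tc$basis
  # zero scores, zero noise: uniform mean level inside the ROI
  z <- matrix(0, 3, nrow(patternLoadings(basis)))
  imgs0 <- renderImages(tpl, basis, z, noise_sigma = 0, seed = 1L)
  roi <- templateLabels(tpl) == 1
  expect_true(all(imageValues(imgs0[[1]])[roi] == basis@mean_level))
  expect_true(all(imageValues(imgs0[[1]])[!roi] == 0))

  # zero-noise generative identity: projection recovers the true scores
  S <- tc$cohort$scores$better
  imgs <- renderImages(tpl, basis, S, noise_sigma = 0, seed = 1L)
  vm <- extractVoxelMatrix(imgs, tpl, 1L)
  rec <- sweep(voxelData(vm), 2, basis@mean_level) %*%
    t(patternLoadings(basis))
  expect_lt(max(abs(rec - S)), 1e-8)

  expect_error(renderImages(tpl, basis, S[, 1:2], noise_sigma = 0),
               class = "pclasso_shape_error")
})

test_that("PCA on noisy rendered cohorts recovers the planted patterns", {
  hits <- 0L
  for (s in 1:5) {
    tc <- tinyCohort(seed = 100L + s,
                     kinds = c("global_positive", "ap_gradient"))
    imgs <- renderImages(tc$template, tc$basis, tc$cohort$scores$better,
                         noise_sigma = tc$spec$noise_sigma, seed = 200L + s)
    pcd <- fitPCA(extractVoxelMatrix(imgs, tc$template, 1L))
    sim <- compareLoadings(pcd, tc$basis, top_k = 2)
    if (all(diag(sim) >= 0.95)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("fixtures round-trip through the readers losslessly", {
  tc <- tinyCohort(seed = 21L, n = 6L)
  imgs <- renderImages(tc$template, tc$basis, tc$cohort$scores,
                       noise_sigma = tc$spec$noise_sigma, seed = 31L)
  dir <- withr::local_tempdir()
  manifest <- writeFixture(tc$cohort, imgs, dir, tc$template)
  expect_identical(manifest$seed, tc$spec$seed)
  fx <- readFixture(dir)
  expect_identical(fx$manifest$seed, tc$spec$seed)
  expect_equal(nrow(fx$clinical), 6L)
  expect_identical(templateLabels(fx$template), templateLabels(tc$template))
  vmIn <- extractVoxelMatrix(imgs$worse, tc$template, 1L)
  vmOut <- extractVoxelMatrix(fx$images$worse, fx$template, 1L)
  expect_equal(voxelData(vmOut)[order(vmOut@subject_ids), ],
               voxelData(vmIn)[order(vmIn@subject_ids), ],
               tolerance = 1e-6, ignore_attr = TRUE)
})
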