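# A fitted decomposition + CV model on a deterministic phantom, shared by
# the estimator tests.
estFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tc <- tinyCohort(seed = 23L)
      imgs <- renderImages(tc$template, tc$basis, tc$cohort$scores$better,
                           noise_sigma = tc$spec$noise_sigma, seed = 3L)
      vm <- extractVoxelMatrix(imgs, tc$template, 1L)
      pcd <- fitPCA(vm)
      design <- patternScores(pcd)[, 1:5]
      y <- tc$cohort$clinical$LMS_better
      cv <- repeatedHoldoutCV(design, y, n_splits = 40L, seed = 4L,
                              outcome_name = "LMS_better")
      cache <<- list(tc = tc, vm = vm, pcd = pcd, design = design, y = y,
                     cv = cv)
    }
    cache
  }
})

test_that("the estimator map is the beta-weighted loading sum", {
  fx <- estFixture()
  pcd <- fx$pcd
  mkModel <- function(betas) {
    new("LassoModel", beta0 = 0.5, betas = betas, lambda = 0,
        active_set = names(betas)[betas != 0])
  }
  # all-zero imaging coefficients give the zero map
  z <- mkModel(c(PC1 = 0, PC2 = 0))
  expect_true(all(computeEstimator(pcd, z)@v == 0))
  # a single unit coefficient reproduces that loading
  one <- mkModel(c(PC1 = 1))
  expect_lt(max(abs(computeEstimator(pcd, one)@v -
                      patternLoadings(pcd)[1, ])), 1e-12)
  # linearity over retained terms
  two <- mkModel(c(PC1 = 0.5, PC3 = -0.2))
  vref <- 0.5 * patternLoadings(pcd)[1, ] - 0.2 * patternLoadings(pcd)[3, ]
  expect_lt(max(abs(computeEstimator(pcd, two)@v - vref)), 1e-12)
  # retained term without a matching loading is a validation error
  deep <- mkModel(setNames(1, sprintf("PC%d", nrow(patternLoadings(pcd)) + 1)))
  expect_error(computeEstimator(pcd, deep),
               class = "pclasso_validation_error")
})

test_that("score-space and voxel-space predictions coincide", {
  fx <- estFixture()
  est <- computeEstimator(fx$pcd, fx$cv@full_model)
  p_scores <- predict(fx$cv@full_model, fx$design)
  p_voxels <- predictFromVoxels(est, fx$vm)
  expect_lt(max(abs(p_scores - p_voxels)), 1e-8)
  # the per-voxel mean predicts the intercept alone
  expect_equal(unname(predictFromVoxels(est, meanVector(fx$pcd))),
               est@beta0, tolerance = 1e-10)
  expect_error(predictFromVoxels(est, rep(1, 5)),
               class = "pclasso_validation_error")
})

test_that("covariate coefficients stay out of the voxel map", {
  fx <- estFixture()
  design <- cbind(fx$design[, 1:3], age = fx$tc$cohort$clinical$age)
  cv <- repeatedHoldoutCV(design, fx$y, n_splits = 25L, seed = 9L)
  est <- computeEstimator(fx$pcd, cv@full_model)
  expect_true("age" %in% names(est@covariate_betas))
  p3 <- predict(cv@full_model, design)
  if (abs(est@covariate_betas["age"]) > 0) {
    expect_error(predictFromVoxels(est, fx$vm),
                 class = "pclasso_validation_error")
  }
  p5 <- predictFromVoxels(est, fx$vm,
                          covariates = cbind(age =
                                               fx$tc$cohort$clinical$age))
  expect_lt(max(abs(p3 - p5)), 1e-8)
})

test_that("maximum-intensity projections separate signs and normalize", {
  grid <- c(8L, 10L, 6L)
  vol <- array(0, grid)
  vol[3, 4, 2] <- 0.7
  mip <- mipRender(vol, "IS")
  expect_equal(mip$positive[3, 4], 1)
  expect_true(all(mip$negative == 0))
  expect_equal(mip$norm_factor, 0.7)
  expect_equal(sum(mip$positive > 0), 1L)
  # antisymmetry under sign flip
  mipNeg <- mipRender(-vol, "IS")
  expect_identical(mipNeg$negative, mip$positive)
  expect_identical(mipNeg$positive, mip$negative)
  # normalization: the joint maximum is 1 for any nonzero map
  vol[5, 5, 5] <- -2.2
  m2 <- mipRender(vol, "AP")
  expect_equal(max(m2$positive, m2$negative), 1)
  expect_warning(m0 <- mipRender(array(0, grid), "LM"), "all-zero")
  expect_true(all(m0$positive == 0) && all(m0$negative == 0))
})

test_that("estimator maps round-trip to NIfTI with a JSON sidecar", {
  fx <- estFixture()
  est <- computeEstimator(fx$pcd, fx$cv@full_model)
  prefix <- file.path(withr::local_tempdir(), "est_test")
  writeEstimatorMap(est, fx$tc$template, prefix)
  img <- readParametricImage(paste0(prefix, ".nii.gz"), kind = "weights")
  vol <- embedVoxels(est@v, voxelIndex(est),
                     dim(templateLabels(fx$tc$template)))
  expect_equal(imageValues(img), vol, tolerance = 1e-6)
  side <- jsonlite::fromJSON(paste0(prefix, ".json"))
  expect_equal(side$beta0, est@beta0, tolerance = 1e-9)
})
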