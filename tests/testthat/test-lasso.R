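test_that("standardization z-scores, records and re-applies", {
  d <- randomDesign(25, 4, seed = 41)
  std <- standardizeDesign(d$X * 3 + 2)
  expect_lt(max(abs(colMeans(std$x))), 1e-10)
  expect_lt(max(abs(apply(std$x, 2, sd) - 1)), 1e-10)
  expect_equal(applyStandardization(d$X * 3 + 2, std$record), std$x)
  withCst <- cbind(d$X, cst = 5)
  expect_warning(s2 <- standardizeDesign(withCst), "constant")
  expect_false("cst" %in% colnames(s2$x))
  expect_error(standardizeDesign(matrix(1, 4, 2)),
               class = "pclasso_validation_error")
})

test_that("the one-predictor toy follows its closed-form path", {
  X <- matrix(c(1, -1), 2, 1, dimnames = list(NULL, "x1"))
  y <- c(1, -1)
  expect_equal(lambdaMax(X, y), 2, tolerance = 1e-10)
  for (lam in c(0, 0.5, 1, 1.5, 2)) {
    m <- lassoSolve(X, y, lam)
    expect_equal(unname(m@betas), max(1 - lam / 2, 0), tolerance = 1e-10)
  }
  expect_equal(unname(lassoSolve(X, y, 1)@betas), 0.5, tolerance = 1e-10)
})

test_that("lambda = 0 reduces to ordinary least squares", {
  for (s in 1:3) {
    d <- randomDesign(30, 5, seed = 500 + s)
    y <- d$y + d$X[, 1] * 2
    m <- lassoSolve(d$X, y, 0)
    ols <- lm(y ~ d$X)
    expect_equal(unname(m@betas), unname(coef(ols)[-1]), tolerance = 1e-6)
    expect_equal(m@beta0, unname(coef(ols)[1]), tolerance = 1e-6)
  }
})

test_that("at and above lambda_max the model is intercept-only", {
  d <- randomDesign(20, 5, seed = 77)
  std <- standardizeDesign(d$X)
  lm0 <- lambdaMax(std$x, d$y)
  for (lam in c(lm0, lm0 * 1.5)) {
    m <- lassoSolve(std$x, d$y, lam)
    expect_identical(m@active_set, character(0))
    expect_equal(m@beta0, mean(d$y), tolerance = 1e-12)
  }
  # homogeneity and the zero-correlation degenerate case
  expect_equal(lambdaMax(std$x, 3 * d$y), 3 * lm0, tolerance = 1e-10)
  expect_equal(lambdaMax(std$x, rep(2, 20)), 0)
})

test_that("solutions satisfy the KKT conditions and match the grid oracle", {
  for (s in 1:6) {
    n <- sample(4:8, 1)
    j <- sample(1:3, 1)
    d <- randomDesign(n, j, seed = 700 + s)
    std <- standardizeDesign(d$X)
    lam <- runif(1, 0, lambdaMax(std$x, d$y))
    m <- lassoSolve(std$x, d$y, lam)
    expect_lt(max(kktResiduals(m, std$x, d$y)), 1e-6)
    oracle <- gridSearchLasso(std$x, d$y, lam)
    expect_lt(abs(lassoObjective(std$x, d$y, m@beta0, m@betas, lam) -
                    oracle$objective), 1e-6)
  }
})

test_that("the solver agrees with an independent LASSO implementation", {
  skip_if_not_installed("glmnet")
  d <- randomDesign(40, 6, seed = 123)
  y <- d$y + 1.5 * d$X[, 2] - 0.8 * d$X[, 5]
  std <- standardizeDesign(d$X)
  n <- nrow(std$x)
  for (lam in c(5, 15, 30)) {
    m <- lassoSolve(std$x, y, lam)
    g <- glmnet::glmnet(std$x, y, lambda = lam / n, standardize = FALSE,
                        thresh = 1e-14)
    expect_equal(unname(m@betas), as.numeric(coef(g))[-1], tolerance = 1e-4)
  }
})

test_that("the penalty grid is linear from zero to lambda_max", {
  g <- lambdaGrid(2, 100)
  expect_length(g, 101)
  expect_equal(g[1], 0)
  expect_equal(g[101], 2)
  expect_equal(unique(round(diff(g), 12)), 0.02)
  expect_true(all(diff(g) >= 0))
  expect_warning(g0 <- lambdaGrid(0, 10), "grid")
  expect_true(all(g0 == 0))
})

test_that("holdout splits have the stated size and reproduce from the seed", {
  sp <- makeSplits(40, n_splits = 50, holdout_fraction = 0.3, seed = 5)
  expect_true(all(vapply(sp$test_indices, length, 1L) == 12L))
  sp2 <- makeSplits(40, n_splits = 50, holdout_fraction = 0.3, seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp$test_indices[[1]], sp$test_indices[[2]]))
})

test_that("repeated holdout CV is reproducible and matches the constant
           model at lambda_max", {
  tc <- tinyCohort(seed = 19L)
  imgs <- renderImages(tc$template, tc$basis, tc$cohort$scores$better,
                       noise_sigma = tc$spec$noise_sigma, seed = 2L)
  pcd <- fitPCA(extractVoxelMatrix(imgs, tc$template, 1L))
  design <- patternScores(pcd)[, 1:5]
  y <- tc$cohort$clinical$aDD
  cv1 <- repeatedHoldoutCV(design, y, n_splits = 40L, seed = 6L,
                           outcome_name = "aDD")
  cv2 <- repeatedHoldoutCV(design, y, n_splits = 40L, seed = 6L,
                           outcome_name = "aDD")
  expect_identical(cv1@mse_test_mean, cv2@mse_test_mean)
  expect_identical(cv1@lambda_min, cv2@lambda_min)
  expect_true(cv1@lambda_min %in% cv1@lambda_grid)

  splits <- makeSplits(length(y), 40L, 0.3, 6L)
  refs <- fitReferenceModels(rowMeans(voxelData(
    extractVoxelMatrix(imgs, tc$template, 1L))), y, splits)
  # at lambda_max the LASSO is intercept-only, i.e. the constant model
  expect_equal(cv1@mse_test_mean[length(cv1@lambda_grid)],
               refs$constant@mse_test_mean, tolerance = 1e-10)
  expect_error(repeatedHoldoutCV(design[1:8, ], y[1:8]),
               class = "pclasso_validation_error")
})

test_that("lambda_min selection prefers sparsity on ties", {
  grid <- seq(0, 2, length.out = 5)
  expect_equal(selectLambdaMin(c(3, 1, 2, 2, 3), grid), 0.5)
  expect_equal(selectLambdaMin(rep(1, 5), grid), 2)      # flat curve
  expect_equal(selectLambdaMin(c(1, 1, 2, 1, 1), grid), 2)
})

test_that("reference models compute their closed-form quantities", {
  splits <- makeSplits(12, n_splits = 25, holdout_fraction = 0.3, seed = 3)
  y <- c(0, 2, rep(1, 10)) + rnorm(12, 0, 0.3)
  br <- rnorm(12)
  refs <- fitReferenceModels(br, y, splits)
  expect_equal(refs$constant@full_model$beta0, mean(y))
  # constant-model MSE_all is the biased sample variance of the outcome
  expect_equal(refs$constant@mse_all, mean((y - mean(y))^2),
               tolerance = 1e-12)
  # noiseless linear outcome: the mean-BR model fits exactly
  lin <- 2 + 3 * br
  refsLin <- fitReferenceModels(br, lin, splits)
  expect_lt(refsLin$mean_br@mse_all, 1e-10)
  expect_lt(refsLin$mean_br@mse_test_mean, 1e-10)
})

test_that("post-selection significance excludes shrunk inputs and bounds
           degenerate p-values", {
  d <- randomDesign(30, 4, seed = 404)
  y <- 2 + 3 * d$X[, 1]                    # noiseless single-signal outcome
  std <- standardizeDesign(d$X)
  lam <- 0.5 * lambdaMax(std$x, y)
  full <- lassoSolve(std$x, y, lam, standardization = std$record)
  cv <- new("CVResult", model_type = "pclasso", lambda_grid = c(0, lam),
            mse_test_mean = c(1, 2), mse_test_se = c(0, 0), lambda_min = lam,
            mse_all = 0, coef_mean = numeric(), coef_sd = numeric(),
            retained_terms = full@active_set, full_model = full,
            n_splits = 1L, holdout_fraction = 0.3, seed = 1L,
            outcome_name = "y")
  pv <- coefficientSignificance(cv, d$X, y)
  expect_identical(names(pv), full@active_set)
  expect_true(all(pv >= .Machine$double.xmin))
  expect_lt(pv["x1"], 1e-10)
  cv@retained_terms <- character(0)
  expect_length(coefficientSignificance(cv, d$X, y), 0)
})
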