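#' Random holdout split sequence
#'
#' Draws \code{n_splits} independent train/test partitions: each test set
#' is round(holdout_fraction * n) subjects sampled without replacement. A
#' single master seed spawns one child seed per split, so the same sequence
#' can be shared between model families.
#'
#' @param n number of subjects.
#' @param n_splits number of random splits (default 500).
#' @param holdout_fraction test fraction (default 0.3).
#' @param seed master seed.
#' @return list(test_indices = list of integer vectors, n, n_splits,
#'   holdout_fraction, seed).
#' @export
makeSplits <- function(n, n_splits = 500L, holdout_fraction = 0.3,
                       seed = 1L) {
  n_test <- round(holdout_fraction * n)
  if (n_test < 1 || n_test >= n)
    stopf("holdout fraction %g leaves no usable test or training set",
          holdout_fraction, class = "pclasso_validation_error")
  seeds <- childSeeds(seed, n_splits)
  idx <- lapply(seeds, function(s) withSeed(s, sample.int(n, n_test)))
  list(test_indices = idx, n = as.integer(n), n_splits = as.integer(n_splits),
       holdout_fraction = holdout_fraction, seed = as.integer(seed))
}

#' Select the penalty minimizing mean test MSE
#'
#' Ties are broken toward the larger penalty (the sparser model).
#'
#' @param cv_result a \linkS4class{CVResult}, or a numeric vector of mean
#'   test MSEs (then \code{grid} must be given).
#' @param grid the penalty grid when \code{cv_result} is a bare vector.
#' @return lambda_min, a member of the grid.
#' @export
selectLambdaMin <- function(cv_result, grid = NULL) {
  if (methods::is(cv_result, "CVResult")) {
    mse <- cv_result@mse_test_mean
    grid <- cv_result@lambda_grid
  } else mse <- cv_result
  grid[max(which(mse == min(mse)))]
}

#' Repeated random-holdout cross-validation of the PC-LASSO model
#'
#' For every penalty on a linear grid from 0 to lambda_max (computed once
#' on the full standardized data), the model is fitted on each training
#' split -- with the standardization recomputed on that split -- and scored
#' by squared error on the held-out subjects. The mean and standard error
#' of the test MSE over splits select lambda_min; the full-data fit at
#' lambda_min provides the retained terms and MSE_all. Per-split
#' coefficients at lambda_min (on the raw input scale, so they are
#' comparable across splits) give the coefficient mean/SD; post-selection
#' p-values come from \code{\link{coefficientSignificance}}.
#'
#' @param design raw (unstandardized) N x J matrix of named inputs: PC
#'   scores and any clinical covariates. All inputs are standardized and
#'   penalized equally.
#' @param outcome numeric(N) clinical metric.
#' @param n_splits,holdout_fraction,seed split settings (defaults 500, 0.3);
#'   ignored when \code{splits} is supplied.
#' @param steps penalty grid steps (default 100 giving 101 values).
#' @param splits optional shared split sequence from
#'   \code{\link{makeSplits}}.
#' @param outcome_name label stored on the result.
#' @return a \linkS4class{CVResult} with model_type "pclasso".
#' @export
repeatedHoldoutCV <- function(design, outcome, n_splits = 500L,
                              holdout_fraction = 0.3, steps = 100L,
                              seed = 1L, splits = NULL,
                              outcome_name = "outcome") {
  X <- as.matrix(design)
  N <- nrow(X)
  if (N < 10) stopf("cross-validation requires N >= 10",
                    class = "pclasso_validation_error")
  if (is.null(splits))
    splits <- makeSplits(N, n_splits, holdout_fraction, seed)
  J <- ncol(X)
  n_train <- N - length(splits$test_indices[[1]])
  if (n_train < J + 2)
    stopf("training splits have %d samples; need at least J + 2 = %d",
          n_train, J + 2, class = "pclasso_validation_error")

  std <- standardizeDesign(X)
  lmax <- lambdaMax(std$x, outcome)
  grid <- lambdaGrid(lmax, steps)

  nS <- splits$n_splits
  mse <- matrix(NA_real_, nS, length(grid))
  coefArr <- array(NA_real_, c(nS, length(grid), J),
                   dimnames = list(NULL, NULL, colnames(std$x)))
  for (s in seq_len(nS)) {
    te <- splits$test_indices[[s]]
    tr <- setdiff(seq_len(N), te)
    stdTr <- standardizeDesign(X[tr, , drop = FALSE])
    path <- lassoPath(stdTr$x, outcome[tr], grid)
    Zte <- applyStandardization(X[te, , drop = FALSE], stdTr$record)
    pred <- sweep(Zte %*% t(path$betas), 2, path$beta0, `+`)
    mse[s, ] <- colMeans((outcome[te] - pred)^2)
    # raw-scale per-split coefficients for cross-split comparability
    coefArr[s, , colnames(stdTr$x)] <-
      sweep(path$betas, 2, stdTr$record$scale, "/")
  }
  mseMean <- colMeans(mse)
  mseSE <- apply(mse, 2, stats::sd) / sqrt(nS)
  lmin <- selectLambdaMin(mseMean, grid)
  li <- max(which(grid == lmin))

  full <- lassoSolve(std$x, outcome, lmin, standardization = std$record,
                     outcome_name = outcome_name)
  mseAll <- mean((outcome - predict(full, X))^2)
  cm <- apply(coefArr[, li, , drop = FALSE], 3, mean, na.rm = TRUE)
  csd <- apply(coefArr[, li, , drop = FALSE], 3, stats::sd, na.rm = TRUE)

  cv <- methods::new("CVResult", model_type = "pclasso",
                     lambda_grid = grid, mse_test_mean = mseMean,
                     mse_test_se = mseSE, lambda_min = lmin,
                     mse_all = mseAll, coef_mean = cm, coef_sd = csd,
                     retained_terms = full@active_set, full_model = full,
                     n_splits = nS,
                     holdout_fraction = splits$holdout_fraction,
                     seed = splits$seed, outcome_name = outcome_name,
                     metadata = list(
                       lambda_max = lmax,
                       coef_scale = "raw input scale (beta_std / sd_train)"))
  cv@p_values <- coefficientSignificance(cv, X, outcome)
  cv@metadata$p_value_method <-
    "two-sided t-tests from a post-selection OLS refit on the active set"
  cv
}

#' Post-selection significance of retained coefficients
#'
#' Refits an ordinary least-squares model restricted to the active set of
#' the full-data fit at lambda_min and reports two-sided t-test p-values.
#' Inputs shrunk to zero are excluded. With an empty active set an empty
#' vector is returned. Degenerate noiseless fits are reported as bounded at
#' the smallest representable double.
#'
#' @param cv_result a \linkS4class{CVResult} holding the full-data fit.
#' @param design,outcome the raw data the CV was run on.
#' @return named numeric p-values over the active set.
#' @export
coefficientSignificance <- function(cv_result, design, outcome) {
  active <- cv_result@retained_terms
  if (!length(active)) return(stats::setNames(numeric(0), character(0)))
  X <- as.matrix(design)[, active, drop = FALSE]
  fit <- stats::lm(outcome ~ X)
  ct <- stats::summary.lm(fit)$coefficients
  pv <- ct[-1, "Pr(>|t|)"]
  pv[!is.finite(pv)] <- 0
  pv <- pmax(pv, .Machine$double.xmin)
  stats::setNames(as.numeric(pv), active)
}

.refCV <- function(type, predictor, outcome, splits, outcome_name) {
  N <- length(outcome)
  nS <- splits$n_splits
  mse <- numeric(nS)
  slope <- numeric(nS)
  for (s in seq_len(nS)) {
    te <- splits$test_indices[[s]]
    tr <- setdiff(seq_len(N), te)
    if (type == "constant") {
      pred <- mean(outcome[tr])
      mse[s] <- mean((outcome[te] - pred)^2)
    } else {
      cf <- stats::coef(stats::lm.fit(cbind(1, predictor[tr]), outcome[tr]))
      slope[s] <- cf[2]
      mse[s] <- mean((outcome[te] - cf[1] - cf[2] * predictor[te])^2)
    }
  }
  if (type == "constant") {
    b0 <- mean(outcome)
    mseAll <- mean((outcome - b0)^2)
    fullm <- list(beta0 = b0)
    cm <- csd <- stats::setNames(numeric(0), character(0))
    retained <- character(0)
  } else {
    cf <- stats::coef(stats::lm.fit(cbind(1, predictor), outcome))
    mseAll <- mean((outcome - cf[1] - cf[2] * predictor)^2)
    fullm <- list(beta0 = unname(cf[1]), beta_mean_br = unname(cf[2]))
    cm <- c(mean_BR = mean(slope))
    csd <- c(mean_BR = stats::sd(slope))
    retained <- "mean_BR"
  }
  methods::new("CVResult", model_type = type, lambda_grid = numeric(0),
               mse_test_mean = mean(mse),
               mse_test_se = stats::sd(mse) / sqrt(nS),
               lambda_min = NA_real_, mse_all = mseAll, coef_mean = cm,
               coef_sd = csd, retained_terms = retained, full_model = fullm,
               n_splits = nS, holdout_fraction = splits$holdout_fraction,
               seed = splits$seed, outcome_name = outcome_name)
}

#' Reference models on shared splits
#'
#' Fits the two baselines the PC-LASSO model is compared against on the
#' exact same split sequence: a constant model (training-mean prediction,
#' indicating absence of meaningful prediction) and a one-predictor
#' least-squares model on the mean ROI BR.
#'
#' @param mean_br numeric(N) mean BR per subject over the ROI.
#' @param outcome numeric(N) clinical metric.
#' @param splits split sequence from \code{\link{makeSplits}} (shared with
#'   the PC-LASSO run).
#' @param outcome_name label.
#' @return list(constant = , mean_br = ) of \linkS4class{CVResult}s.
#' @export
fitReferenceModels <- function(mean_br, outcome, splits,
                               outcome_name = "outcome") {
  list(constant = .refCV("constant", NULL, outcome, splits, outcome_name),
       mean_br = .refCV("mean_br", mean_br, outcome, splits, outcome_name))
}

#' Model comparison table
#'
#' One row per fitted outcome/side combination with the columns of the
#' standard comparison schema: predicted metric, input side, MSE_test mean
#' +/- SE and MSE_all for the constant, mean-BR and PC-LASSO models, and
#' the retained PC-LASSO terms.
#'
#' @param rows list of lists, each with elements outcome, side, constant,
#'   mean_br, pclasso (CVResults).
#' @return data.frame.
#' @export
cvSummaryTable <- function(rows) {
  mt <- function(cv) {
    i <- if (length(cv@lambda_grid))
      max(which(cv@lambda_grid == cv@lambda_min)) else 1L
    c(cv@mse_test_mean[i], cv@mse_test_se[i])
  }
  do.call(rbind, lapply(rows, function(r) {
    a <- mt(r$constant); b <- mt(r$mean_br); c <- mt(r$pclasso)
    data.frame(predicted_metric = r$outcome, input_side = r$side,
               mse_test_constant = a[1], mse_test_se_constant = a[2],
               mse_all_constant = r$constant@mse_all,
               mse_test_mean_br = b[1], mse_test_se_mean_br = b[2],
               mse_all_mean_br = r$mean_br@mse_all,
               mse_test_pclasso = c[1], mse_test_se_pclasso = c[2],
               mse_all_pclasso = r$pclasso@mse_all,
               retained_terms = if (length(r$pclasso@retained_terms))
                 paste(r$pclasso@retained_terms, collapse = "+")
               else "none",
               stringsAsFactors = FALSE)
  }))
}

#' Trace-plot data
#'
#' Full-data coefficient paths and the cross-validated test MSE curve as a
#' long-format data.frame, ready for export.
#'
#' @param cv_result a PC-LASSO \linkS4class{CVResult}.
#' @param design,outcome the raw data the CV was run on.
#' @return data.frame with lambda, mse_test_mean, mse_test_se and one
#'   column per coefficient (full-data fit, standardized scale).
#' @export
traceData <- function(cv_result, design, outcome) {
  std <- standardizeDesign(as.matrix(design))
  path <- lassoPath(std$x, outcome, cv_result@lambda_grid)
  out <- data.frame(lambda = cv_result@lambda_grid,
                    mse_test_mean = cv_result@mse_test_mean,
                    mse_test_se = cv_result@mse_test_se)
  cbind(out, as.data.frame(path$betas))
}

#' Predicted-versus-actual data
#'
#' @param cv_result a \linkS4class{CVResult} (PC-LASSO or mean-BR).
#' @param design raw design matrix (PC-LASSO) or mean-BR vector.
#' @param outcome actual metric values.
#' @return data.frame(subject, actual, predicted).
#' @export
predictedVsActual <- function(cv_result, design, outcome) {
  pred <- if (cv_result@model_type == "pclasso")
    predict(cv_result@full_model, as.matrix(design))
  else if (cv_result@model_type == "mean_br")
    cv_result@full_model$beta0 +
      cv_result@full_model$beta_mean_br * as.numeric(design)
  else rep(cv_result@full_model$beta0, length(outcome))
  data.frame(subject = seq_along(outcome), actual = outcome,
             predicted = pred)
}
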