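#' Standardize a design matrix
#'
#' Z-scores each column and records the statistics so the same
#' transformation can be re-applied to new data (the L1 penalty is
#' scale-sensitive, so predictors are standardized before fitting).
#' Columns with zero standard deviation are dropped with a warning.
#'
#' @param design_matrix numeric matrix with column names.
#' @return list(x = standardized matrix, record = list(center, scale,
#'   kept)).
#' @export
standardizeDesign <- function(design_matrix) {
  X <- as.matrix(design_matrix)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 1e-12
  if (!any(keep))
    stopf("all design columns are constant", class = "pclasso_validation_error")
  if (!all(keep))
    warnf("dropping constant design column(s): %s",
          paste(colnames(X)[!keep], collapse = ", "))
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  list(x = Z, record = list(center = ctr[keep], scale = scl[keep],
                            kept = colnames(X)[keep]))
}

#' Re-apply a stored standardization record
#'
#' @param design_matrix raw matrix containing (at least) the recorded
#'   columns.
#' @param record the record from \code{\link{standardizeDesign}}.
#' @return standardized matrix over the recorded columns.
#' @export
applyStandardization <- function(design_matrix, record) {
  X <- as.matrix(design_matrix)[, record$kept, drop = FALSE]
  sweep(sweep(X, 2, record$center), 2, record$scale, "/")
}

.softThreshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Smallest penalty giving an intercept-only model
#'
#' Under the objective 0.5 * RSS + lambda * L1 with a free intercept, the
#' all-zero coefficient vector is optimal iff lambda >=
#' max_j |sum_n x_nj (y_n - mean(y))|; that bound is returned.
#'
#' @param X standardized design matrix.
#' @param y outcome vector.
#' @return lambda_max (>= 0).
#' @export
lambdaMax <- function(X, y) {
  max(abs(crossprod(as.matrix(X), y - mean(y))))
}

#' Linear penalty grid from 0 to lambda_max
#'
#' @param lambda_max upper end (from \code{\link{lambdaMax}}).
#' @param steps number of steps (default 100, giving 101 grid values).
#' @return nondecreasing numeric vector of steps + 1 values.
#' @export
lambdaGrid <- function(lambda_max, steps = 100L) {
  if (lambda_max < 0) stopf("lambda_max must be >= 0")
  if (steps < 1) stopf("steps must be >= 1")
  if (lambda_max == 0) {
    warnf("lambda_max is 0; grid is all zeros")
    return(rep(0, steps + 1))
  }
  seq(0, lambda_max, length.out = steps + 1)
}

# Core cyclic coordinate descent on centered data via the Gram matrix.
# Returns list(beta, n_iter, converged).
.cdSolve <- function(G, c0, lambda, beta, tol = 1e-8, max_sweeps = 100000L) {
  J <- length(c0)
  dG <- diag(G)
  for (sweep_i in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(J)) {
      if (dG[j] <= 0) { beta[j] <- 0; next }
      zj <- c0[j] - sum(G[j, ] * beta) + dG[j] * beta[j]
      bj <- .softThreshold(zj, lambda) / dG[j]
      delta <- max(delta, abs(bj - beta[j]))
      beta[j] <- bj
    }
    if (delta < tol)
      return(list(beta = beta, n_iter = sweep_i, converged = TRUE))
  }
  list(beta = beta, n_iter = max_sweeps, converged = FALSE)
}

#' Solve the L1-penalized least-squares problem
#'
#' Minimizes 0.5 * sum_n (y_n - beta0 - sum_j x_nj beta_j)^2 +
#' lambda * sum_j |beta_j| with an unpenalized intercept, by cyclic
#' coordinate descent with soft-thresholding on the centered problem.
#' Convergence: maximum coefficient change below \code{tol} within a sweep.
#' At lambda = 0 the solution equals ordinary least squares; at lambda >=
#' \code{\link{lambdaMax}} all non-intercept coefficients are zero and the
#' intercept equals the outcome mean.
#'
#' @param X design matrix (standardized by convention; any columns
#'   accepted).
#' @param y outcome vector.
#' @param lambda penalty, >= 0.
#' @param beta_init optional warm start.
#' @param tol convergence tolerance on coefficient changes (default 1e-8).
#' @param max_sweeps sweep budget before a convergence error is raised.
#' @param standardization optional record stored on the model for later
#'   back-transformation to raw input scale.
#' @param outcome_name stored on the model.
#' @return a \linkS4class{LassoModel}.
#' @export
lassoSolve <- function(X, y, lambda, beta_init = NULL, tol = 1e-8,
                       max_sweeps = 100000L, standardization = list(),
                       outcome_name = NA_character_) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  assertFinite(X, "design"); assertFinite(y, "outcome")
  if (lambda < 0) stopf("lambda must be >= 0")
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  yc <- y - mean(y)
  G <- crossprod(Xc)
  c0 <- drop(crossprod(Xc, yc))
  beta <- beta_init %||% rep(0, ncol(X))
  sol <- .cdSolve(G, c0, lambda, beta, tol = tol, max_sweeps = max_sweeps)
  if (!sol$converged)
    stopf("coordinate descent did not converge in %d sweeps (lambda=%g)",
          max_sweeps, lambda, class = "pclasso_fit_error")
  betas <- stats::setNames(sol$beta, colnames(X))
  methods::new("LassoModel",
               beta0 = mean(y) - sum(xbar * sol$beta),
               betas = betas, lambda = lambda,
               active_set = names(betas)[abs(betas) > 0],
               standardization = standardization,
               outcome_name = outcome_name, n_iter = sol$n_iter)
}

#' Coefficient path over a penalty grid
#'
#' Fits the solver along the grid from the largest penalty down with warm
#' starts. Used for trace plots and by the cross-validation loop.
#'
#' @param X design matrix.
#' @param y outcome.
#' @param grid penalty grid (see \code{\link{lambdaGrid}}).
#' @return list(betas = length(grid) x J matrix, beta0 = numeric, grid).
#' @export
lassoPath <- function(X, y, grid) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  yc <- y - mean(y)
  G <- crossprod(Xc)
  c0 <- drop(crossprod(Xc, yc))
  ord <- order(grid, decreasing = TRUE)
  B <- matrix(0, length(grid), ncol(X),
              dimnames = list(NULL, colnames(X)))
  beta <- rep(0, ncol(X))
  for (idx in ord) {
    sol <- .cdSolve(G, c0, grid[idx], beta)
    if (!sol$converged)
      stopf("path fit did not converge at lambda=%g", grid[idx],
            class = "pclasso_fit_error")
    beta <- sol$beta
    B[idx, ] <- beta
  }
  list(betas = B, beta0 = mean(y) - drop(B %*% xbar), grid = grid)
}

#' Karush-Kuhn-Tucker residuals of a LASSO solution
#'
#' For active coefficients the stationarity residual is
#' |x_j' r - lambda * sign(beta_j)|; for inactive ones the violation of
#' |x_j' r| <= lambda. All residuals are ~0 at an exact solution.
#'
#' @param model a \linkS4class{LassoModel} fitted on \code{X}, \code{y}.
#' @param X,y the data the model was fitted on.
#' @return named numeric of per-coefficient residuals.
#' @export
kktResiduals <- function(model, X, y) {
  X <- as.matrix(X)
  r <- y - model@beta0 - drop(X %*% model@betas)
  g <- drop(crossprod(X, r))
  res <- ifelse(abs(model@betas) > 0,
                abs(g - model@lambda * sign(model@betas)),
                pmax(abs(g) - model@lambda, 0))
  stats::setNames(res, names(model@betas))
}

#' Predict from a LASSO model
#'
#' Applies the model's stored standardization record (if any) to new raw
#' data before the linear predictor.
#'
#' @param object a \linkS4class{LassoModel}.
#' @param newdata matrix or data.frame of raw inputs.
#' @param ... ignored.
#' @export
setMethod("predict", "LassoModel", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (length(object@standardization))
    X <- applyStandardization(X, object@standardization)
  else X <- X[, names(object@betas), drop = FALSE]
  drop(object@beta0 + X %*% object@betas)
})

#' Map model coefficients back to raw input scale
#'
#' @param model a \linkS4class{LassoModel} with a standardization record.
#' @return list(beta0, betas) on the raw input scale.
#' @export
rawScaleCoef <- function(model) {
  if (!length(model@standardization))
    return(list(beta0 = model@beta0, betas = model@betas))
  rec <- model@standardization
  b <- model@betas[rec$kept] / rec$scale
  list(beta0 = model@beta0 - sum(b * rec$center), betas = b)
}
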