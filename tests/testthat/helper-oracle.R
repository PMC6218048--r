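# Independent oracles, deliberately implemented without reusing any package
# internals.

# Penalized objective with the intercept profiled out (for fixed beta the
# optimal intercept is mean(y - X beta), so the centered form is exact).
lassoObjectiveCentered <- function(Xc, yc, beta, lambda) {
  r <- yc - drop(Xc %*% beta)
  0.5 * sum(r^2) + lambda * sum(abs(beta))
}

lassoObjective <- function(X, y, beta0, beta, lambda) {
  r <- y - beta0 - drop(as.matrix(X) %*% beta)
  0.5 * sum(r^2) + lambda * sum(abs(beta))
}

# Dense factorial coefficient-grid search, iteratively refined around the
# running optimum (the objective is convex, so refinement converges to the
# global minimum); final per-axis resolution < 1e-4.
gridSearchLasso <- function(X, y, lambda, lo = -5, hi = 5, points = 21L,
                            rounds = 8L) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  J <- ncol(X)
  center <- rep(0, J)
  width <- hi - lo
  best <- NULL
  for (r in seq_len(rounds)) {
    axes <- lapply(seq_len(J), function(j)
      seq(max(lo, center[j] - width / 2), min(hi, center[j] + width / 2),
          length.out = points))
    grid <- as.matrix(expand.grid(axes))
    R <- Xc %*% t(grid)
    obj <- 0.5 * colSums((yc - R)^2) + lambda * rowSums(abs(grid))
    i <- which.min(obj)
    center <- grid[i, ]
    best <- list(beta = center, objective = obj[i])
    width <- width * 2 / (points - 1) * 2  # keep a margin around the optimum
  }
  best$beta0 <- mean(y) - sum(colMeans(X) * best$beta)
  best
}

# Brute-force PCA oracle: eigendecomposition of the sample covariance.
bruteForcePCA <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc), symmetric = TRUE)
  keep <- seq_len(min(nrow(X) - 1, ncol(X)))
  list(loadings = t(ev$vectors[, keep, drop = FALSE]),
       vaf = 100 * ev$values[keep] / sum(diag(crossprod(Xc))))
}

absCos <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
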