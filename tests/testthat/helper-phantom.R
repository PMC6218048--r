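# Small phantom builders shared across test files.

tinyTemplate <- function() {
  makeTemplate(grid_shape = c(16L, 24L, 16L),
               roi_geometry = list(
                 putamen = list(center = c(5, 11, 8), radii = c(3, 7, 4)),
                 caudate = list(center = c(11, 14, 9), radii = c(2, 3, 5))))
}

# deterministic two-pattern cohort on the tiny template
tinyCohort <- function(seed = 11L, noise_sigma = 0.1, n = 40L,
                       kinds = c("global_positive", "ap_gradient",
                                 "is_gradient")) {
  tpl <- tinyTemplate()
  basis <- makePlantedBasis(tpl, kinds = kinds)
  K <- length(kinds)
  spec <- cohortSpec(n_subjects = n,
                     score_model = data.frame(
                       intercept = c(12, rep(0, K - 1)),
                       slope = c(-1.5, rep(0, K - 1)),
                       sd = c(1, 3, 2)[seq_len(K)]),
                     lms_model = list(intercept = 6,
                                      coefficients = c(-0.5, 0, 1.2)[seq_len(K)],
                                      sd = 0.4),
                     asymmetry_offset = c(-2, rep(0, K - 1)),
                     noise_sigma = noise_sigma, seed = seed)
  coh <- sampleCohort(spec, basis)
  list(template = tpl, basis = basis, spec = spec, cohort = coh)
}

randomDesign <- function(n, j, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * j), n, j,
                dimnames = list(NULL, paste0("x", seq_len(j))))
    y <- rnorm(n)
    list(X = X, y = y)
  })
}
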