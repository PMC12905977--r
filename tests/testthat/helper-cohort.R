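# Shared fixtures: standard covariate set and a one-call cohort +
# preprocessing bundle used across test files.

probe_covariates <- c("age", "sex", "batch", "slide",
                      paste0("cell_", 1:5), "smoking_score")

# simulate + residualize in one go; returns cohort, residual phenotype and
# standardized marker sets ready for the samplers
make_prepared_cohort <- function(..., seed = 1) {
  cfg <- sim_config(..., seed = seed)
  co <- simulate_cohort(cfg)
  y <- residualize_phenotype(co$phenotype, co$covariates)
  W <- suppressWarnings(
    residualize_markers(co$methylation, co$covariates, cols = probe_covariates))
  Z <- suppressWarnings(residualize_markers(co$genotypes))
  list(cohort = co, y = y, dnam = W, snp = Z)
}

# short MCMC settings for unit-scale fits
quick_mcmc <- function(seed = 1, n_iter = 600, burn_in = 200) {
  mcmc_spec(n_iter = n_iter, burn_in = burn_in, thin = 2, n_chains = 1,
            seed = seed)
}

# independent REML oracle: restricted-likelihood grid search over the
# variance fraction after eigen-rotation, profiling total variance
helper_grid_oracle <- function(y, K, grid = seq(0.01, 0.99, by = 0.01)) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  yr <- crossprod(eg$vectors, y)
  Xr <- crossprod(eg$vectors, matrix(1, n, 1))
  ll <- vapply(grid, function(h) {
    lam <- h * eg$values + (1 - h)
    Vi <- 1 / lam
    XtViX <- sum(Xr^2 * Vi)
    b <- sum(Xr * yr * Vi) / XtViX
    r <- yr - Xr %*% b
    s2 <- sum(r^2 * Vi) / (n - 1)
    -0.5 * (sum(log(lam)) + (n - 1) * log(s2) + log(XtViX))
  }, numeric(1))
  grid[which.max(ll)]
}
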