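# The single-marker conjugate case is the gating correctness test for the
# Gibbs sampler: with fixed residual variance and fixed mixture weights the
# posterior is available in closed form.
test_that("single-marker sampler matches the closed-form conjugate posterior", {
  set.seed(2)
  n <- 200
  z <- as.vector(scale(rnorm(n)))
  y <- z * 0.3 + rnorm(n, sd = 1)
  vy <- var(y)
  frac <- 0.2                       # slab variance as fraction of Var(y)
  pi0 <- 0.5
  fit <- fit_bayesr(y, dnam = matrix(z, dimnames = list(NULL, "m1")),
                    prior = mixture_prior(component_fracs = frac,
                                          fix_pi = c(pi0, 1 - pi0)),
                    mcmc = mcmc_spec(n_iter = 6000, burn_in = 1000, thin = 1,
                                     n_chains = 1, seed = 9),
                    fix_resid_var = 1 / vy)

  # analytic oracle on the unit-variance scale of y
  ys <- as.vector(scale(y))
  s2e <- 1 / vy
  zz <- sum(z^2)
  rhs <- sum(z * ys)
  s2b <- frac
  post_var <- 1 / (zz / s2e + 1 / s2b)
  bhat <- rhs / (zz + s2e / s2b)
  logBF <- -0.5 * log1p(zz * s2b / s2e) +
    0.5 * rhs^2 * s2b / (s2e * (s2e + zz * s2b))
  pip_an <- (1 - pi0) * exp(logBF) / ((1 - pi0) * exp(logBF) + pi0)

  expect_equal(unname(fit$pip$dnam), pip_an, tolerance = 0.02)
  # mixture posterior mean = PIP * slab mean; draws are iid here, so the
  # Monte-Carlo SE follows from the mixture variance
  mix_mean <- pip_an * bhat
  mix_var <- pip_an * (post_var + bhat^2) - mix_mean^2
  mcse <- sqrt(mix_var / fit$n_draws)
  expect_lt(abs(unname(fit$beta_mean$dnam) / sd(y) - mix_mean), 3 * mcse)
})

test_that("input contracts are enforced", {
  set.seed(3)
  n <- 100
  W <- matrix(rnorm(n * 5) * 3, n, 5, dimnames = list(NULL, paste0("m", 1:5)))
  y <- rnorm(n)
  expect_error(fit_bayesr(y, dnam = W), "standardized")
  expect_error(fit_bayesr(rnorm(20), dnam = scale(W[1:20, ])), "n >= 50")
  expect_error(fit_bayesr(y), "at least one marker set")
  expect_error(mixture_prior(component_fracs = c(0.01, 0.001)), NULL)
  expect_error(mcmc_spec(n_iter = 100, burn_in = 100), NULL)
})

test_that("fits are reproducible and chain-seed invariant at summary level", {
  d <- make_prepared_cohort(n_individuals = 800, n_probes = 400, n_snps = 80,
                            var_frac_dnam = 0.3, var_frac_snp = 0,
                            class_probs_dnam = c(0.85, 0.1, 0.04, 0.01),
                            mqtl_frac = 0, seed = 21)
  f1 <- fit_bayesr(d$y, dnam = d$dnam, mcmc = quick_mcmc(seed = 5))
  f2 <- fit_bayesr(d$y, dnam = d$dnam, mcmc = quick_mcmc(seed = 5))
  expect_identical(f1$var_frac, f2$var_frac)        # same seed, same draws
  f3 <- fit_bayesr(d$y, dnam = d$dnam, mcmc = quick_mcmc(seed = 99))
  expect_lt(abs(f1$var_frac[["dnam"]] - f3$var_frac[["dnam"]]), 0.02)
  # permuting marker storage order leaves the set-level summary intact
  perm <- sample(ncol(d$dnam$values))
  Wp <- d$dnam$values[, perm]
  f4 <- fit_bayesr(d$y, dnam = Wp, mcmc = quick_mcmc(seed = 5))
  expect_lt(abs(f1$var_frac[["dnam"]] - f4$var_frac[["dnam"]]), 0.02)
})

test_that("per-draw fractions decompose to one and PIPs are consistent", {
  d <- make_prepared_cohort(n_individuals = 300, n_probes = 150, n_snps = 100,
                            var_frac_dnam = 0.25, var_frac_snp = 0.4,
                            mqtl_frac = 0, seed = 8)
  fit <- fit_bayesr(d$y, dnam = d$dnam, snp = d$snp, mcmc = quick_mcmc(seed = 2))
  expect_equal(unname(rowSums(fit$samples)), rep(1, fit$n_draws),
               tolerance = 1e-10)
  expect_true(all(fit$pip$dnam >= 0 & fit$pip$dnam <= 1))
  for (s in fit$sets) {
    expect_equal(sum(fit$class_counts[s, ]), sum(fit$pip[[s]]),
                 tolerance = 1e-6)
  }
  expect_true(all(fit$cri95[1, ] <= fit$var_frac + 1e-12))
  expect_true(all(fit$cri95[2, ] >= fit$var_frac - 1e-12))
})

test_that("pip_hits thresholds and sorts", {
  fake <- structure(list(pip = list(dnam = c(a = 0.99, b = 0.96, c = 0.80)),
                         sets = "dnam"), class = "bayesr")
  expect_equal(names(pip_hits(fake, "dnam", 0.95)), c("a", "b"))
  fake0 <- structure(list(pip = list(dnam = c(a = 0, b = 0)), sets = "dnam"),
                     class = "bayesr")
  expect_length(pip_hits(fake0, "dnam"), 0)
  expect_error(pip_hits(fake, "dnam", 1.2), "threshold")
  expect_error(pip_hits(fake, "nope"), "unknown marker set")
})

test_that("architecture table behaves under null and planted single effect", {
  # nearly uninformative regime (n small relative to the class variances):
  # the posterior class counts revert to the symmetric Dirichlet(1,..,1)
  # prior expectation of p/4 markers per class
  set.seed(5)
  n <- 60
  p <- 40
  W <- scale(matrix(rnorm(n * p), n, p))
  colnames(W) <- paste0("m", 1:p)
  f <- fit_bayesr(rnorm(n), dnam = W,
                  mcmc = mcmc_spec(n_iter = 2000, burn_in = 500, thin = 2,
                                   n_chains = 1, seed = 3))
  tab <- architecture_table(f)
  expect_true(all(tab$expected_markers > 0.5 * p / 4 &
                  tab$expected_markers < 1.5 * p / 4))

  # informative null: whatever the class occupancy, the variance shares
  # attributed to every class are near zero
  set.seed(12)
  n <- 1000
  p <- 400
  W <- scale(matrix(rnorm(n * p), n, p))
  colnames(W) <- paste0("m", 1:p)
  f0 <- fit_bayesr(rnorm(n), dnam = W,
                   mcmc = mcmc_spec(n_iter = 800, burn_in = 300, thin = 2,
                                    n_chains = 1, seed = 3))
  tab0 <- architecture_table(f0)
  expect_true(all(abs(tab0$var_share) < 0.05))
  expect_true(all(tab0$expected_markers >= 0))

  # one planted strong probe lands in the large class with expected count
  # near one (mixture weights held sparse to test the class assignment
  # itself, not the weight learning)
  d <- make_prepared_cohort(n_individuals = 2000, n_probes = 30, n_snps = 50,
                            var_frac_dnam = 0.04, var_frac_snp = 0,
                            class_probs_dnam = c(1, 0, 0, 0),
                            plant_large_dnam = 1, equal_class_effects = TRUE,
                            mqtl_frac = 0, seed = 14)
  f1 <- fit_bayesr(d$y, dnam = d$dnam,
                   prior = mixture_prior(fix_pi = c(0.94, 0.02, 0.02, 0.02)),
                   mcmc = mcmc_spec(n_iter = 1000, burn_in = 300, thin = 2,
                                    n_chains = 1, seed = 4))
  tab1 <- architecture_table(f1)
  large <- tab1$expected_markers[tab1$class == "large"]
  expect_gt(large, 0.5)
  expect_lt(large, 1.5)
  expect_equal(sum(tab1$expected_markers), sum(f1$pip$dnam), tolerance = 1e-6)
})
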