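test_that("phenotype residualization projects out the design exactly", {
  set.seed(1)
  n <- 200
  cov <- data.frame(age = runif(n, 20, 80), sex = rbinom(n, 1, 0.5))
  # perfect fit: phenotype a linear function of the design
  expect_lt(max(abs(residualize_phenotype(2 * cov$age, cov))), 1e-10)
  # idempotence: an already-orthogonal phenotype comes back centred
  y <- rnorm(n)
  r1 <- residualize_phenotype(y, cov)
  r2 <- residualize_phenotype(r1, cov)
  expect_equal(r1, r2, tolerance = 1e-10)
  # residuals orthogonal to design columns
  expect_lt(abs(sum(r1 * cov$age)), 1e-8 * n)
  expect_lt(abs(sum(r1 * cov$sex)), 1e-8 * n)
})

test_that("rank-deficient designs are rejected with the collinear column", {
  set.seed(2)
  n <- 100
  cov <- data.frame(age = runif(n, 20, 80), sex = rbinom(n, 1, 0.5))
  cov$age_copy <- cov$age
  expect_error(residualize_phenotype(rnorm(n), cov, extra = "age_copy"),
               "collinear.*age_copy")
})

test_that("generator sex effect is recovered by the phenotype regression", {
  co <- simulate_cohort(sim_config(n_individuals = 2000, n_probes = 50,
                                   n_snps = 50, seed = 9))
  fit <- stats::lm(co$phenotype ~ age + I(age^2) + sex, data = co$covariates)
  expect_equal(unname(stats::coef(fit)["sex"]), 14, tolerance = 0.5)
})

test_that("marker residualization standardizes and drops degenerate columns", {
  set.seed(3)
  n <- 150
  cov <- data.frame(age = runif(n, 20, 80), sex = rbinom(n, 1, 0.5),
                    batch = factor(sample(1:3, n, TRUE)))
  m <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("m", 1:10)))
  # a column equal to a batch indicator has zero residual variance
  m[, 4] <- as.numeric(cov$batch == 2)
  expect_warning(rz <- residualize_markers(m, cov), "dropped")
  expect_false("m4" %in% rz$marker_ids)
  expect_lt(max(abs(colMeans(rz$values))), 1e-8)
  expect_lt(max(abs(apply(rz$values, 2, var) - 1)), 1e-6)
  # residual columns orthogonal to every covariate column
  X <- stats::model.matrix(~ age + sex + batch, cov)
  expect_lt(max(abs(crossprod(X, rz$values))), 1e-6 * n)
  # intercept-only: plain z-scores
  z <- residualize_markers(m[, 1:3])
  expect_equal(z$values, scale(m[, 1:3])[, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("relationship matrix equals the brute-force pair sum", {
  set.seed(4)
  Z <- scale(matrix(rnorm(50 * 200), 50, 200))
  colnames(Z) <- paste0("m", 1:200)
  K <- relationship_matrix(Z, "ORM")
  brute <- matrix(0, 50, 50)
  for (i in 1:50) for (k in 1:50) brute[i, k] <- sum(Z[i, ] * Z[k, ]) / 200
  expect_equal(unname(K$values), brute, tolerance = 1e-10)
  expect_true(isSymmetric(K$values))
  expect_equal(mean(diag(K$values)), 1, tolerance = 0.1)
  # chunked accumulation identical
  K2 <- relationship_matrix(Z, "ORM", chunk_size = 17)
  expect_equal(K$values, K2$values, tolerance = 1e-12)
  # duplicated individuals produce off-diagonal equal to the diagonals
  Zd <- rbind(Z, Z[1, ])
  Kd <- relationship_matrix(Zd, "ORM")
  expect_equal(Kd$values[1, 51], Kd$values[1, 1], tolerance = 1e-10)
})

test_that("relationship matrix construction commutes with column order", {
  set.seed(5)
  Z <- scale(matrix(rnorm(40 * 60), 40, 60))
  colnames(Z) <- paste0("m", 1:60)
  perm <- sample(60)
  expect_equal(relationship_matrix(Z, "ORM")$values,
               relationship_matrix(Z[, perm], "ORM")$values,
               tolerance = 1e-12)
})

test_that("allele-frequency standardization matches the GRM convention", {
  set.seed(6)
  maf <- runif(30, 0.1, 0.5)
  G <- sapply(maf, function(p) rbinom(100, 2, p))
  colnames(G) <- paste0("s", 1:30)
  z <- standardize_genotypes(G)
  p <- colMeans(G) / 2
  expect_equal(z$values,
               sweep(sweep(G, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/"),
               tolerance = 1e-12, ignore_attr = TRUE)
  Gm <- cbind(G, mono = rep(0, 100))
  expect_warning(standardize_genotypes(Gm), "monomorphic")
})

test_that("unrelatedness filter is correct on crafted and random matrices", {
  # identity: everyone kept
  expect_equal(filter_unrelated(diag(5)), 1:5)
  # one related pair: the higher index of the pair is removed
  K <- diag(6)
  K[2, 5] <- K[5, 2] <- 0.5
  expect_equal(filter_unrelated(K, 0.05), c(1, 2, 3, 4, 6))
  expect_error(filter_unrelated(diag(3), 0), "positive")

  # independent greedy oracle + feasibility on random matrices
  greedy_oracle <- function(K, thr) {
    A <- K >= thr
    diag(A) <- FALSE
    alive <- rep(TRUE, nrow(K))
    repeat {
      deg <- rowSums(A[, alive, drop = FALSE]) * alive
      if (all(deg == 0)) break
      worst <- which(deg == max(deg))
      rm <- worst[length(worst)]
      alive[rm] <- FALSE
      A[rm, ] <- FALSE
      A[, rm] <- FALSE
    }
    which(alive)
  }
  set.seed(7)
  for (rep in 1:20) {
    K <- matrix(runif(64, -0.1, 0.2), 8, 8)
    K <- (K + t(K)) / 2
    diag(K) <- 1
    kept <- filter_unrelated(K, 0.05)
    sub <- K[kept, kept, drop = FALSE]
    diag(sub) <- 0
    expect_true(all(sub < 0.05))              # feasibility, exact
    expect_equal(kept, greedy_oracle(K, 0.05))
  }
})

test_that("mean imputation fills missing cells explicitly", {
  m <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2, dimnames = list(NULL, c("a", "b")))
  out <- impute_mean(m)
  expect_equal(unname(out[2, 1]), 2)       # mean of 1 and 3
  expect_equal(attr(out, "n_imputed"), 1L)
  expect_error(impute_mean(matrix(NA_real_, 2, 1)), "entirely missing")
  expect_error(residualize_markers(m), "missing")
})
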