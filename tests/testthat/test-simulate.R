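test_that("null architecture gives zero effects and pure noise phenotype", {
  cfg <- sim_config(n_individuals = 400, n_probes = 100, n_snps = 100,
                    var_frac_dnam = 0, var_frac_snp = 0, seed = 3)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$beta_m == 0))
  expect_true(all(co$truth$beta_g == 0))
  expect_equal(unname(co$truth$realized_var_frac[c("dnam", "snp")]), c(0, 0))
  # phenotype variance on the unit signal scale is residual only
  y <- residualize_phenotype(co$phenotype, co$covariates)
  expect_equal(stats::var(y / cfg$pheno_sd_cm), 1, tolerance = 0.15)
})

test_that("same config and seed reproduces the cohort bitwise", {
  cfg <- sim_config(n_individuals = 150, n_probes = 80, n_snps = 60, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$truth$beta_m, b$truth$beta_m)
})

test_that("true linear predictors recover the target variance fractions", {
  # oracle: OLS of the residualized phenotype on the generator's own true
  # linear predictors
  co <- simulate_cohort(sim_config(n_individuals = 5000, n_probes = 400,
                                   n_snps = 400, var_frac_dnam = 0.25,
                                   var_frac_snp = 0.55, mqtl_frac = 0,
                                   seed = 7))
  y <- residualize_phenotype(co$phenotype, co$covariates) / co$truth$pheno_scale_cm
  fit <- stats::lm(y ~ co$truth$g_dnam + co$truth$g_snp)
  b <- stats::coef(fit)
  r2_m <- stats::var(b[2] * co$truth$g_dnam) / stats::var(y)
  r2_g <- stats::var(b[3] * co$truth$g_snp) / stats::var(y)
  expect_equal(unname(r2_m), 0.25, tolerance = 0.02)
  expect_equal(unname(r2_g), 0.55, tolerance = 0.02)
})

test_that("realized variance fractions track targets across seeds", {
  fr <- sapply(1:8, function(s) {
    co <- simulate_cohort(sim_config(n_individuals = 600, n_probes = 150,
                                     n_snps = 150, seed = s))
    co$truth$realized_var_frac[c("dnam", "snp")]
  })
  se <- apply(fr, 1, stats::sd) / sqrt(ncol(fr))
  expect_lt(abs(mean(fr["dnam", ]) - 0.25), 2 * se["dnam"] + 0.01)
  expect_lt(abs(mean(fr["snp", ]) - 0.55), 2 * se["snp"] + 0.01)
})

test_that("driver SNPs explain close to mqtl_r2 of adjusted probe variance", {
  co <- simulate_cohort(sim_config(n_individuals = 2000, n_probes = 300,
                                   n_snps = 300, mqtl_frac = 0.3,
                                   mqtl_r2 = 0.2, seed = 5))
  W <- suppressWarnings(
    residualize_markers(co$methylation, co$covariates, cols = probe_covariates))
  r2 <- mapply(function(pr, sn) stats::cor(W$values[, pr], co$genotypes[, sn])^2,
               co$truth$mqtl_probe, co$truth$mqtl_snp)
  expect_equal(mean(r2), 0.2, tolerance = 0.05)
})

test_that("covariate structure is well formed", {
  co <- simulate_cohort(sim_config(n_individuals = 300, n_probes = 50,
                                   n_snps = 50, seed = 2))
  cells <- as.matrix(co$covariates[, grep("^cell_", names(co$covariates))])
  expect_true(all(abs(rowSums(cells) - 1) < 1e-8))
  expect_true(all(co$methylation >= 0 & co$methylation <= 1))
  expect_true(all(co$genotypes %in% 0:2))
  # conditional Gaussianity of the phenotype given covariates; a polygenic
  # architecture keeps the marker contribution close to normal
  co2 <- simulate_cohort(sim_config(n_individuals = 1000, n_probes = 400,
                                    n_snps = 200,
                                    class_probs_dnam = c(0.6, 0.3, 0.08, 0.02),
                                    class_probs_snp = c(0.6, 0.3, 0.08, 0.02),
                                    seed = 2))
  y <- residualize_phenotype(co2$phenotype, co2$covariates)
  expect_gt(stats::shapiro.test(y)$p.value, 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(var_frac_dnam = 0.5, var_frac_snp = 0.5),
               "residual variance")
  expect_error(sim_config(class_probs_dnam = c(0.5, 0.5, 0.2, 0)),
               "summing to 1")
  expect_error(sim_config(mqtl_r2 = 1), "mqtl_r2")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(var_frac_dnam = 0.2,
                          class_probs_dnam = c(1, 0, 0, 0)),
               "unattainable")
})

test_that("cohorts round-trip through the on-disk format", {
  co <- simulate_cohort(sim_config(n_individuals = 10, n_probes = 20,
                                   n_snps = 20, var_frac_dnam = 0,
                                   var_frac_snp = 0, seed = 4))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_error(write_cohort(co, dir), "overwrite")
  back <- read_cohort(dir)
  expect_equal(back$methylation, co$methylation, tolerance = 1e-12,
               ignore_attr = "values")
  expect_equal(back$genotypes, co$genotypes, tolerance = 1e-12,
               ignore_attr = "values")
  expect_equal(back$phenotype, co$phenotype, tolerance = 1e-12)
  expect_equal(back$covariates$age, co$covariates$age, tolerance = 1e-12)
  # genotype TSV: 10 data rows, id column + 20 SNP columns
  g <- readLines(file.path(dir, "genotypes.tsv"))
  expect_length(g, 11)
  expect_length(strsplit(g[1], "\t")[[1]], 21)
})

test_that("writing an empty cohort errors instead of emitting empty files", {
  co <- simulate_cohort(sim_config(n_individuals = 5, n_probes = 5,
                                   n_snps = 5, var_frac_dnam = 0,
                                   var_frac_snp = 0, seed = 1))
  co$ids <- character(0)
  expect_error(write_cohort(co, withr::local_tempdir(), overwrite = TRUE),
               "empty cohort")
})
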