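#' Configuration for a synthetic cohort
#'
#' Bundles and validates all parameters of the cohort generator. The
#' generator emulates a population cohort with array methylation, SNP
#' genotypes and a heritable quantitative trait (height, in cm): a fixed
#' fraction of phenotypic variance is attributable to standardized probe
#' effects and a fixed fraction to standardized SNP effects, a subset of
#' probes is driven by a cis-SNP (mQTL coupling), and height additionally
#' carries age and sex fixed effects plus technical confounders (batch,
#' slide, cell-type proportions, a smoking score).
#'
#' Marker effects are drawn from discrete size classes \{null, small,
#' medium, large\} whose variances stand in ratio 1:10:100
#' (small:medium:large), mirroring the effect-size classes of the Bayesian
#' variance-partitioning model.
#'
#' @param n_individuals,n_probes,n_snps cohort dimensions.
#' @param var_frac_dnam fraction of phenotypic variance from probe effects.
#' @param var_frac_snp fraction of phenotypic variance from SNP effects.
#' @param class_probs_dnam,class_probs_snp probabilities over the
#'   \{null, small, medium, large\} effect classes (length 4, sums to 1).
#' @param mqtl_frac fraction of probes with a cis-SNP driver.
#' @param mqtl_r2 fraction of a driven probe's latent (logit-scale) variance
#'   explained by its driver SNP.
#' @param maf_range interval from which minor-allele frequencies are drawn;
#'   must lie in (0, 0.5].
#' @param n_batches number of processing batches (also used for slides).
#' @param cell_alpha Dirichlet concentration for cell-type proportions.
#' @param age_range age sampling interval in years.
#' @param sex_effect_cm male minus female mean height, cm. The default of
#'   14 cm matches the male-female gap in large adult cohorts.
#' @param age_effect_cm_per_year linear age slope on height, cm/year.
#' @param pheno_sd_cm standard deviation (cm) of height after removing age
#'   and sex, used to place the unit-variance signal model on the cm scale.
#' @param dnam_effect_corr_sex correlation between male and female probe
#'   effect vectors; 1 (default) means a single shared architecture, 0 means
#'   independent architectures per sex.
#' @param plant_large_dnam force exactly this many randomly chosen probes
#'   into the large effect class (overriding their class draw); useful for
#'   discovery-power studies with a controlled number of strong probes.
#' @param equal_class_effects if `TRUE`, effects within a class all have
#'   the class magnitude with random sign instead of a normal draw, so
#'   every planted marker carries an equal variance share.
#' @param seed integer seed for the single RNG stream of the generator.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 1000,
                       n_probes = 1000,
                       n_snps = 1500,
                       var_frac_dnam = 0.25,
                       var_frac_snp = 0.55,
                       class_probs_dnam = c(null = 0.95, small = 0.03,
                                            medium = 0.015, large = 0.005),
                       class_probs_snp = c(null = 0.95, small = 0.04,
                                           medium = 0.009, large = 0.001),
                       mqtl_frac = 0.2,
                       mqtl_r2 = 0.2,
                       maf_range = c(0.05, 0.5),
                       n_batches = 4,
                       cell_alpha = c(6, 3, 2, 1, 1),
                       age_range = c(18, 93),
                       sex_effect_cm = 14,
                       age_effect_cm_per_year = -0.05,
                       pheno_sd_cm = 6.7,
                       dnam_effect_corr_sex = 1,
                       plant_large_dnam = 0L,
                       equal_class_effects = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_probes = as.integer(n_probes),
    n_snps = as.integer(n_snps),
    var_frac_dnam = var_frac_dnam,
    var_frac_snp = var_frac_snp,
    class_probs_dnam = class_probs_dnam,
    class_probs_snp = class_probs_snp,
    mqtl_frac = mqtl_frac,
    mqtl_r2 = mqtl_r2,
    maf_range = maf_range,
    n_batches = as.integer(n_batches),
    cell_alpha = cell_alpha,
    age_range = age_range,
    sex_effect_cm = sex_effect_cm,
    age_effect_cm_per_year = age_effect_cm_per_year,
    pheno_sd_cm = pheno_sd_cm,
    dnam_effect_corr_sex = dnam_effect_corr_sex,
    plant_large_dnam = as.integer(plant_large_dnam),
    equal_class_effects = equal_class_effects,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_individuals >= 1, cfg$n_probes >= 1, cfg$n_snps >= 1)
  if (cfg$var_frac_dnam < 0 || cfg$var_frac_snp < 0)
    stop("variance fractions must be nonnegative")
  if (cfg$var_frac_dnam + cfg$var_frac_snp >= 1)
    stop("var_frac_dnam + var_frac_snp must be < 1 (residual variance must be positive)")
  for (nm in c("class_probs_dnam", "class_probs_snp")) {
    p <- cfg[[nm]]
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(nm, " must be 4 nonnegative probabilities summing to 1")
  }
  if (cfg$mqtl_frac < 0 || cfg$mqtl_frac > 1) stop("mqtl_frac must be in [0, 1]")
  if (cfg$mqtl_r2 < 0 || cfg$mqtl_r2 >= 1) stop("mqtl_r2 must be in [0, 1)")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  if (cfg$plant_large_dnam < 0) stop("plant_large_dnam must be >= 0")
  if (cfg$var_frac_dnam > 0 && cfg$class_probs_dnam[1] >= 1 &&
      cfg$plant_large_dnam == 0)
    stop("var_frac_dnam > 0 is unattainable with all-null probe classes")
  if (cfg$var_frac_snp > 0 && cfg$class_probs_snp[1] >= 1)
    stop("var_frac_snp > 0 is unattainable with all-null SNP classes")
  if (abs(cfg$dnam_effect_corr_sex) > 1)
    stop("dnam_effect_corr_sex must be in [-1, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d individuals, %d probes, %d SNPs\n",
              x$n_individuals, x$n_probes, x$n_snps))
  cat(sprintf("  variance fractions: DNAm %.3f, SNP %.3f, residual %.3f\n",
              x$var_frac_dnam, x$var_frac_snp,
              1 - x$var_frac_dnam - x$var_frac_snp))
  cat(sprintf("  mQTL: %.0f%% of probes driven, r2 = %.2f; seed = %d\n",
              100 * x$mqtl_frac, x$mqtl_r2, x$seed))
  invisible(x)
}

# Effect-size class variances in ratio 1:10:100 (small:medium:large);
# class 0 is the null.
.class_var_ratio <- c(0, 1, 10, 100)

# Draw per-marker effects by class, on an arbitrary scale; rescaling to the
# target variance fraction happens against the realized linear predictor.
.draw_class_effects <- function(p, class_probs, plant_large = 0L,
                                equal = FALSE) {
  cls <- sample.int(4L, p, replace = TRUE, prob = class_probs) - 1L
  if (plant_large > 0) {
    if (plant_large > p) stop("cannot plant more large effects than markers")
    cls[sample.int(p, plant_large)] <- 3L
  }
  mult <- if (equal) sign(stats::runif(p) - 0.5) else stats::rnorm(p)
  eff <- mult * sqrt(.class_var_ratio[cls + 1L])
  list(class = cls, effect = eff)
}

logit <- function(p) log(p / (1 - p))
logistic <- function(x) 1 / (1 + exp(-x))

#' Simulate a synthetic cohort with known ground truth
#'
#' Draws genotypes, methylation, covariates and a height phenotype under
#' the generative model described in [sim_config()]. Draw order from the
#' single RNG stream (seeded by `config$seed`) is fixed: allele
#' frequencies, genotypes, sex, age, batch, slide, cell proportions,
#' smoking score, probe baselines, mQTL assignment, probe noise and
#' confounder loadings, probe effect classes/effects, SNP effect
#' classes/effects, residual, polygenic-score noise.
#'
#' Methylation is generated additively on the logit scale and mapped to
#' beta values in \[0,1\] by the logistic function, which keeps values
#' bounded while remaining near-linear in the bulk. For a probe with a
#' cis-driver SNP, the driver explains `mqtl_r2` of the probe's latent
#' variance. Marker effects act on the column-standardized matrices and the
#' realized linear predictors are rescaled so the probe and SNP
#' contributions carry exactly `var_frac_dnam` and `var_frac_snp` of the
#' unit target variance; the residual is drawn at the complementary
#' variance, so realized fractions fluctuate around the targets.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `cohort_data`: list with `genotypes` (n x p_g
#'   dosages in \[0,2\]), `methylation` (n x p_m betas in \[0,1\]),
#'   `phenotype` (height, cm), `covariates` (data.frame: age, sex, batch,
#'   slide, cell proportions, smoking_score, pgs), `ids`, and a `truth`
#'   block holding the effect vectors, class labels, mQTL map and realized
#'   variance fractions.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  p_m <- config$n_probes
  p_g <- config$n_snps

  ids <- sprintf("id_%05d", seq_len(n))
  snp_ids <- sprintf("snp_%05d", seq_len(p_g))
  probe_ids <- sprintf("cg%06d", seq_len(p_m))

  ## genotypes: binomial(2, maf) dosages
  maf <- stats::runif(p_g, config$maf_range[1], config$maf_range[2])
  G <- matrix(stats::rbinom(n * p_g, 2L, rep(maf, each = n)),
              nrow = n, ncol = p_g, dimnames = list(ids, snp_ids))

  ## demographic + technical covariates
  sex <- stats::rbinom(n, 1L, 0.5)              # 1 = male
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  batch <- sample.int(config$n_batches, n, replace = TRUE)
  slide <- sample.int(config$n_batches * 4L, n, replace = TRUE)
  n_cells <- length(config$cell_alpha)
  cells <- matrix(stats::rgamma(n * n_cells,
                                shape = rep(config$cell_alpha, each = n)),
                  nrow = n)
  cells <- cells / rowSums(cells)
  colnames(cells) <- paste0("cell_", seq_len(n_cells))
  smoking <- stats::rnorm(n)

  ## methylation on the logit scale: baseline + mQTL driver + confounders + noise
  mu <- stats::runif(p_m, logit(0.15), logit(0.85))
  s_lat <- 0.5                                  # latent per-probe SD
  n_mqtl <- round(config$mqtl_frac * p_m)
  mqtl_probe <- if (n_mqtl > 0) sample.int(p_m, n_mqtl) else integer(0)
  mqtl_snp <- if (n_mqtl > 0) sample.int(p_g, n_mqtl, replace = TRUE) else integer(0)
  X_lat <- matrix(stats::rnorm(n * p_m), n, p_m) * s_lat
  if (n_mqtl > 0) {
    g_drv <- scale(G[, mqtl_snp, drop = FALSE])      # sample-standardized drivers
    X_lat[, mqtl_probe] <- sqrt(1 - config$mqtl_r2) * X_lat[, mqtl_probe] +
      sqrt(config$mqtl_r2) * s_lat * g_drv
  }
  batch_eff <- matrix(stats::rnorm(config$n_batches * p_m, sd = 0.1),
                      config$n_batches, p_m)
  cell_load <- stats::rnorm(p_m, sd = 0.2)
  X_lat <- sweep(X_lat, 2, -mu, "-") + batch_eff[batch, , drop = FALSE] +
    outer(scale(cells[, 1])[, 1], cell_load)
  M <- logistic(X_lat)
  dimnames(M) <- list(ids, probe_ids)

  ## Marker effects act on covariate-ADJUSTED standardized probes: the
  ## probe signal relevant to the trait is the part not driven by batch,
  ## cell composition or smoking, matching the analysis convention that
  ## probes are adjusted for technical covariates before modelling. SNP
  ## effects act on plain standardized dosages.
  safe_scale <- function(m) {
    s <- scale(m)
    bad <- !is.finite(colSums(s))           # zero-variance columns
    if (any(bad)) s[, bad] <- 0
    s
  }
  D <- stats::model.matrix(~ age + sex + factor(batch) + cells + smoking)
  W <- if (n > ncol(D) + 2) safe_scale(qr.resid(qr(D), M)) else safe_scale(M)
  Z <- safe_scale(G)
  dnam_draw <- .draw_class_effects(p_m, config$class_probs_dnam,
                                   config$plant_large_dnam,
                                   config$equal_class_effects)
  beta_m <- dnam_draw$effect
  beta_m_f <- beta_m
  if (config$dnam_effect_corr_sex < 1) {
    r <- config$dnam_effect_corr_sex
    indep <- stats::rnorm(p_m) * sqrt(.class_var_ratio[dnam_draw$class + 1L])
    beta_m_f <- r * beta_m + sqrt(1 - r^2) * indep
  }
  snp_draw <- .draw_class_effects(p_g, config$class_probs_snp,
                                  equal = config$equal_class_effects)
  beta_g <- snp_draw$effect

  scale_to <- function(g, v) {
    s <- stats::sd(g)
    if (v > 0 && s == 0)
      stop("requested variance fraction unattainable: no non-null effects drawn")
    if (v == 0 || s == 0) list(g = g * 0, mult = 0)
    else list(g = g * sqrt(v) / s, mult = sqrt(v) / s)
  }
  g_m_raw <- as.vector(W %*% beta_m)
  g_m_raw_f <- as.vector(W %*% beta_m_f)
  male <- sex == 1L
  if (config$dnam_effect_corr_sex < 1) {
    g_m_mix <- ifelse(male, g_m_raw, g_m_raw_f)
  } else g_m_mix <- g_m_raw
  sc_m <- scale_to(g_m_mix, config$var_frac_dnam)
  g_m <- sc_m$g
  beta_m <- beta_m * sc_m$mult
  beta_m_f <- beta_m_f * sc_m$mult
  g_g_raw <- as.vector(Z %*% beta_g)
  sc_g <- scale_to(g_g_raw, config$var_frac_snp)
  g_g <- sc_g$g
  beta_g <- beta_g * sc_g$mult

  ## residual drawn orthogonal to the realized linear predictors with exact
  ## variance, so the generative variance fractions are pinned to their
  ## targets up to the (intended, e.g. mQTL-driven) covariance between the
  ## probe and SNP predictors
  resid_var <- 1 - config$var_frac_dnam - config$var_frac_snp
  e <- stats::rnorm(n)
  if (n > 3) {
    e <- qr.resid(qr(cbind(1, g_m, g_g)), e)
    e <- e / stats::sd(e) * sqrt(resid_var)
  } else e <- e * sqrt(resid_var)

  signal <- g_m + g_g + e
  height <- 162 + config$sex_effect_cm * sex +
    config$age_effect_cm_per_year * (age - mean(config$age_range)) +
    config$pheno_sd_cm * signal

  ## Polygenic-score proxy: a noisy version of the TOTAL additive-genetic
  ## value of the trait, i.e. the direct SNP contribution plus the
  ## mQTL-mediated genetic component of the probe contribution — a PGS
  ## trained on a trait GWAS captures genetic influence regardless of
  ## whether it is mediated through methylation.
  g_m_gen <- if (n_mqtl > 0) {
    as.vector(g_drv %*% (beta_m[mqtl_probe] * sqrt(config$mqtl_r2)))
  } else rep(0, n)
  A <- g_g + g_m_gen
  pgs <- if (stats::sd(A) > 0) {
    sqrt(0.7) * as.vector(scale(A)) + sqrt(0.3) * stats::rnorm(n)
  } else stats::rnorm(n)

  covariates <- data.frame(
    id = ids, age = age, sex = sex,
    batch = factor(batch), slide = factor(slide),
    cells, smoking_score = smoking, pgs = pgs,
    stringsAsFactors = FALSE
  )

  var_tot <- stats::var(signal)
  truth <- list(
    beta_m = stats::setNames(beta_m, probe_ids),
    beta_m_female = stats::setNames(beta_m_f, probe_ids),
    beta_g = stats::setNames(beta_g, snp_ids),
    class_dnam = stats::setNames(dnam_draw$class, probe_ids),
    class_snp = stats::setNames(snp_draw$class, snp_ids),
    mqtl_probe = probe_ids[mqtl_probe],
    mqtl_snp = snp_ids[mqtl_snp],
    maf = stats::setNames(maf, snp_ids),
    g_dnam = g_m, g_snp = g_g,
    realized_var_frac = c(
      dnam = stats::var(g_m) / var_tot,
      snp = stats::var(g_g) / var_tot,
      residual = stats::var(e) / var_tot
    ),
    target_var_frac = c(dnam = config$var_frac_dnam,
                        snp = config$var_frac_snp,
                        residual = resid_var),
    pheno_scale_cm = config$pheno_sd_cm
  )

  out <- list(
    genotypes = G, methylation = M, phenotype = height,
    covariates = covariates, ids = ids, truth = truth,
    config = config
  )
  class(out) <- "cohort_data"
  out
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d probes, %d SNPs\n",
              length(x$ids), ncol(x$methylation), ncol(x$genotypes)))
  cat(sprintf("  height: mean %.1f cm (SD %.1f)\n",
              mean(x$phenotype), stats::sd(x$phenotype)))
  rf <- x$truth$realized_var_frac
  cat(sprintf("  realized variance fractions: DNAm %.3f, SNP %.3f, residual %.3f\n",
              rf["dnam"], rf["snp"], rf["residual"]))
  invisible(x)
}
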