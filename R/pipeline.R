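#' Validate a pipeline run configuration
#'
#' A run configuration drives [run_pipeline()] and the per-stage
#' functions. It is a named list (typically read from YAML) with the
#' generator parameters, prior and MCMC blocks, the train/test split and a
#' seed. Unknown keys are rejected before any compute starts.
#'
#' @param config named list or path to a YAML file.
#' @return validated config list with defaults filled in.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    n_individuals = 500, n_probes = 500, n_snps = 800,
    var_frac_dnam = 0.25, var_frac_snp = 0.55,
    mqtl_frac = 0.2, mqtl_r2 = 0.2,
    test_frac = 1 / 3,
    prior = list(component_fracs = c(1e-4, 1e-3, 1e-2),
                 dirichlet_alpha = 1, resid_df = 4),
    mcmc = list(n_iter = 800, burn_in = 300, thin = 2, n_chains = 1),
    # null off-diagonal GRM entries have SD 1/sqrt(p_snps); at desk-scale
    # marker counts the conventional 0.05 cutoff sits inside that noise, so
    # the default is set above it (see the methods vignette)
    grm_threshold = 0.3,
    n_phewas_phenotypes = 20,
    seed = 1L
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (blk in c("prior", "mcmc")) {
    extra <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
    if (length(extra) > 0)
      stop("unknown ", blk, " config key(s): ", paste(extra, collapse = ", "))
    defaults[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  config$prior <- NULL
  config$mcmc <- NULL
  defaults[names(config)] <- config
  stopifnot(defaults$test_frac > 0, defaults$test_frac < 1)
  defaults
}

.stage_path <- function(out_dir, ...) file.path(out_dir, ...)

.require_stage <- function(path, producer) {
  if (!file.exists(path))
    stop("missing upstream artifact ", path,
         "; run the '", producer, "' stage first")
  path
}

#' Pipeline stages
#'
#' Each stage reads its inputs from `out_dir` (written by the previous
#' stage), computes, and writes its outputs back, so a run is resumable
#' and each stage independently testable. [run_pipeline()] chains them:
#' simulate, preprocess, fit-bayesr (marginal DNAm, marginal SNP, joint,
#' joint with polygenic-score-adjusted phenotype), fit-oreml (joint +
#' bivariate cross-sex), score (train/test split), phewas.
#'
#' @param config a [run_config()] list (or YAML path).
#' @param out_dir run directory.
#' @return the stage's main artifact path(s), invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config, out_dir) {
  config <- run_config(config)
  cfg <- sim_config(n_individuals = config$n_individuals,
                    n_probes = config$n_probes, n_snps = config$n_snps,
                    var_frac_dnam = config$var_frac_dnam,
                    var_frac_snp = config$var_frac_snp,
                    mqtl_frac = config$mqtl_frac, mqtl_r2 = config$mqtl_r2,
                    seed = config$seed)
  cohort <- simulate_cohort(cfg)
  write_cohort(cohort, .stage_path(out_dir, "cohort"), overwrite = TRUE)
  invisible(.stage_path(out_dir, "cohort"))
}

#' @rdname pipeline
#' @export
pipeline_preprocess <- function(config, out_dir) {
  config <- run_config(config)
  .require_stage(.stage_path(out_dir, "cohort", "covariates.tsv"), "simulate")
  cohort <- read_cohort(.stage_path(out_dir, "cohort"))
  n <- length(cohort$ids)
  set.seed(config$seed + 1L)
  test <- sort(sample.int(n, round(config$test_frac * n)))
  train <- setdiff(seq_len(n), test)

  y <- residualize_phenotype(cohort$phenotype, cohort$covariates)
  marker_covs <- c("age", "sex", "batch", "slide",
                   grep("^cell_", names(cohort$covariates), value = TRUE),
                   "smoking_score")
  W <- residualize_markers(cohort$methylation, cohort$covariates,
                           cols = marker_covs)
  Z <- standardize_genotypes(cohort$genotypes)
  grm <- relationship_matrix(Z, kind = "GRM")
  keep <- filter_unrelated(grm, threshold = config$grm_threshold)

  pre <- .stage_path(out_dir, "preprocess")
  dir.create(pre, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.frame(id = cohort$ids, y_resid = y,
                                split = ifelse(seq_len(n) %in% test,
                                               "test", "train"),
                                unrelated = seq_len(n) %in% keep),
                     file.path(pre, "phenotype.tsv"), sep = "\t")
  write_marker_matrix(`rownames<-`(W$values, cohort$ids),
                      file.path(pre, "dnam_resid.tsv"))
  write_marker_matrix(`rownames<-`(Z$values, cohort$ids),
                      file.path(pre, "snp_std.tsv"))
  invisible(pre)
}

.load_preprocessed <- function(out_dir, split = NULL) {
  pre <- .stage_path(out_dir, "preprocess")
  .require_stage(file.path(pre, "phenotype.tsv"), "preprocess")
  ph <- data.table::fread(file.path(pre, "phenotype.tsv"), data.table = FALSE)
  W <- data.table::fread(file.path(pre, "dnam_resid.tsv"), data.table = FALSE)
  Z <- data.table::fread(file.path(pre, "snp_std.tsv"), data.table = FALSE)
  to_mat <- function(df) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  W <- to_mat(W)
  Z <- to_mat(Z)
  sel <- if (is.null(split)) ph$unrelated else ph$unrelated & ph$split == split
  restd <- function(m) {
    m <- m[sel, , drop = FALSE]
    m <- sweep(m, 2, colMeans(m), "-")
    sweep(m, 2, sqrt(apply(m, 2, stats::var)), "/")
  }
  list(y = ph$y_resid[sel], ids = ph$id[sel],
       dnam = restd(W), snp = restd(Z), sel = sel)
}

#' @rdname pipeline
#' @export
pipeline_fit_bayesr <- function(config, out_dir) {
  config <- run_config(config)
  d <- .load_preprocessed(out_dir, split = "train")
  cohort <- read_cohort(.stage_path(out_dir, "cohort"))
  prior <- do.call(mixture_prior, config$prior)
  mcmc <- do.call(mcmc_spec, c(config$mcmc, list(seed = config$seed + 2L)))
  fits <- list(
    marginal_dnam = fit_bayesr(d$y, dnam = d$dnam, prior = prior, mcmc = mcmc),
    marginal_snp = fit_bayesr(d$y, snp = d$snp, prior = prior, mcmc = mcmc),
    joint = fit_bayesr(d$y, dnam = d$dnam, snp = d$snp,
                       prior = prior, mcmc = mcmc)
  )
  sel_cov <- cohort$covariates[d$sel, , drop = FALSE]
  y_pgs <- residualize_phenotype(cohort$phenotype[d$sel], sel_cov,
                                 extra = "pgs")
  fits$joint_pgs_adjusted <- fit_bayesr(y_pgs, dnam = d$dnam, snp = d$snp,
                                        prior = prior, mcmc = mcmc)
  bdir <- .stage_path(out_dir, "bayesr")
  dir.create(bdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fits))
    write_report(fits[[nm]], file.path(bdir, paste0(nm, ".json")))
  ws <- weight_set(fits$joint, set = "dnam",
                   train_pheno_mean = mean(cohort$phenotype[d$sel]),
                   train_pheno_sd = stats::sd(cohort$phenotype[d$sel]))
  write_weights(ws, file.path(bdir, "mps_weights.tsv"))
  wg <- weight_set(fits$joint, set = "snp",
                   train_pheno_mean = mean(cohort$phenotype[d$sel]),
                   train_pheno_sd = stats::sd(cohort$phenotype[d$sel]))
  write_weights(wg, file.path(bdir, "pgs_weights.tsv"))
  invisible(bdir)
}

#' @rdname pipeline
#' @export
pipeline_fit_oreml <- function(config, out_dir) {
  config <- run_config(config)
  d <- .load_preprocessed(out_dir, split = "train")
  cohort <- read_cohort(.stage_path(out_dir, "cohort"))
  orm <- relationship_matrix(d$dnam, kind = "ORM")
  grm <- relationship_matrix(d$snp, kind = "GRM")
  fits <- list(
    marginal_dnam = fit_reml(d$y, list(dnam = orm)),
    joint = fit_reml(d$y, list(dnam = orm, snp = grm))
  )
  sex <- cohort$covariates$sex[d$sel]
  fits$bivariate_sex <- fit_bivariate_sex(d$y, sex, orm)
  odir <- .stage_path(out_dir, "oreml")
  dir.create(odir, showWarnings = FALSE, recursive = TRUE)
  write_report(fits[c("marginal_dnam", "joint")],
               file.path(odir, "oreml.json"))
  write_report(fits$bivariate_sex, file.path(odir, "bivariate.json"))
  invisible(odir)
}

#' @rdname pipeline
#' @export
pipeline_score <- function(config, out_dir) {
  config <- run_config(config)
  wfile <- .require_stage(.stage_path(out_dir, "bayesr", "mps_weights.tsv"),
                          "fit-bayesr")
  ws <- read_weights(wfile)
  d <- .load_preprocessed(out_dir, split = "test")
  cohort <- read_cohort(.stage_path(out_dir, "cohort"))
  rep <- score_report(ws, d$dnam, cohort$phenotype[d$sel],
                      cohort$covariates[d$sel, , drop = FALSE])
  sdir <- .stage_path(out_dir, "score")
  dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
  write_report(rep, file.path(sdir, "score_report.json"))
  data.table::fwrite(data.frame(id = d$ids, mps_raw = rep$score_raw,
                                mps_cm = rep$score_cm),
                     file.path(sdir, "mps.tsv"), sep = "\t")
  invisible(sdir)
}

#' Synthesize a phenotype panel for the PheWAS stage
#'
#' Builds a panel of standard-normal phenotypes for PheWAS exercises on a
#' synthetic cohort: a handful correlated with the trait (height proxies),
#' a handful on the DNAm-score path, and the remainder independent noise.
#'
#' @param cohort a `cohort_data`.
#' @param n_phenotypes panel size.
#' @param seed RNG seed.
#' @return data.frame of phenotypes.
#' @export
synthesize_phenotype_panel <- function(cohort, n_phenotypes = 20, seed = 1L) {
  set.seed(seed)
  n <- length(cohort$ids)
  h <- as.vector(scale(cohort$phenotype))
  gm <- if (!is.null(cohort$truth$g_dnam)) {
    as.vector(scale(cohort$truth$g_dnam))
  } else stats::rnorm(n)
  panel <- list()
  n_proxy <- min(4, n_phenotypes)
  n_path <- min(3, max(0, n_phenotypes - n_proxy))
  for (i in seq_len(n_proxy))
    panel[[paste0("height_proxy_", i)]] <-
      0.6 * h + sqrt(1 - 0.36) * stats::rnorm(n)
  for (i in seq_len(n_path))
    panel[[paste0("dnam_path_", i)]] <-
      0.5 * gm + sqrt(0.75) * stats::rnorm(n)
  for (i in seq_len(n_phenotypes - n_proxy - n_path))
    panel[[paste0("null_pheno_", i)]] <- stats::rnorm(n)
  as.data.frame(panel)
}

#' @rdname pipeline
#' @export
pipeline_phewas <- function(config, out_dir) {
  config <- run_config(config)
  mfile <- .require_stage(.stage_path(out_dir, "score", "mps.tsv"), "score")
  mps <- data.table::fread(mfile, data.table = FALSE)
  d <- .load_preprocessed(out_dir, split = "test")
  cohort <- read_cohort(.stage_path(out_dir, "cohort"))
  panel <- synthesize_phenotype_panel(
    list(ids = d$ids, phenotype = cohort$phenotype[d$sel],
         truth = list(g_dnam = cohort$truth$g_dnam[d$sel])),
    n_phenotypes = config$n_phewas_phenotypes, seed = config$seed + 3L)
  tab <- run_phewas(mps$mps_cm, panel,
                    cohort$covariates[d$sel, , drop = FALSE],
                    compare_outcome = cohort$phenotype[d$sel])
  pdir <- .stage_path(out_dir, "phewas")
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  write_report(tab, file.path(pdir, "phewas.json"))
  invisible(pdir)
}

#' Run the full analysis pipeline
#'
#' Chains all stages on a synthetic cohort and writes a run manifest
#' (config, seed, package version) sufficient to reproduce the run.
#'
#' @param config a [run_config()] list or YAML path.
#' @param out_dir run directory (created).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pipeline_simulate(config, out_dir)
  pipeline_preprocess(config, out_dir)
  pipeline_fit_bayesr(config, out_dir)
  pipeline_fit_oreml(config, out_dir)
  pipeline_score(config, out_dir)
  pipeline_phewas(config, out_dir)
  manifest <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("dnamvar")),
    seed = config$seed,
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
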