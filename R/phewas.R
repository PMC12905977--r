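#' Phenome-wide association study of a profile score
#'
#' Regresses the cm-scale score on each phenotype in turn, adjusted for age
#' and sex, with every phenotype mean-centred and scaled to unit variance
#' beforehand (so effect sizes are per SD of the phenotype and comparable
#' across phenotypes). The identical machinery is run with the measured
#' trait as the outcome for side-by-side comparison. Significance uses the
#' Bonferroni threshold `alpha / n_phenotypes_tested`. Complete-case
#' analysis per phenotype; phenotypes with fewer than 3 distinct values
#' after standardization are skipped with a record.
#'
#' @param score cm-scale profile score.
#' @param phenotypes data.frame of phenotype columns (binary phenotypes as
#'   0/1; they are standardized like the rest).
#' @param covariates data.frame with `age` and `sex`.
#' @param alpha family-wise error target (default 0.05).
#' @param compare_outcome optional measured trait (e.g. height) run through
#'   the same regressions for comparison.
#' @return object of class `phewas_table`: data.frame with per-phenotype
#'   `effect`, `se`, `p`, `bonferroni_significant`, `n_used` (and the
#'   parallel `height_*` block when `compare_outcome` is supplied), plus
#'   attributes `alpha`, `threshold`, `skipped`.
#' @export
run_phewas <- function(score, phenotypes, covariates, alpha = 0.05,
                       compare_outcome = NULL) {
  stopifnot(is.data.frame(phenotypes), nrow(phenotypes) == length(score),
            all(c("age", "sex") %in% names(covariates)))
  pheno_names <- setdiff(names(phenotypes), "id")
  age <- covariates$age
  sex <- as.numeric(covariates$sex)

  one_fit <- function(outcome, ph) {
    ok <- stats::complete.cases(outcome, ph, age, sex)
    z <- ph[ok]
    if (length(unique(z)) < 3) return(NULL)
    z <- as.vector(scale(z))
    fit <- stats::lm(outcome[ok] ~ z + age[ok] + sex[ok])
    cf <- summary(fit)$coefficients["z", ]
    c(effect = cf[1], se = cf[2], p = cf[4], n_used = sum(ok))
  }

  rows <- list()
  skipped <- character(0)
  for (nm in pheno_names) {
    res <- one_fit(score, phenotypes[[nm]])
    if (is.null(res)) {
      skipped <- c(skipped, nm)
      next
    }
    row <- data.frame(phenotype = nm, effect = res[1], se = res[2],
                      p = res[3], n_used = res[4], row.names = NULL)
    if (!is.null(compare_outcome)) {
      hres <- one_fit(compare_outcome, phenotypes[[nm]])
      if (is.null(hres)) hres <- rep(NA_real_, 4)
      row$height_effect <- hres[1]
      row$height_se <- hres[2]
      row$height_p <- hres[3]
    }
    rows[[nm]] <- row
  }
  tab <- do.call(rbind, rows)
  n_tested <- nrow(tab)
  threshold <- alpha / n_tested
  tab$bonferroni_significant <- tab$p < threshold
  if (!is.null(compare_outcome))
    tab$height_bonferroni_significant <- tab$height_p < threshold
  rownames(tab) <- NULL
  structure(tab, alpha = alpha, threshold = threshold, skipped = skipped,
            class = c("phewas_table", "data.frame"))
}

#' @export
print.phewas_table <- function(x, ...) {
  cat(sprintf("PheWAS: %d phenotypes tested, Bonferroni threshold %.4g\n",
              nrow(x), attr(x, "threshold")))
  if (length(attr(x, "skipped")))
    cat("  skipped (too few distinct values):",
        paste(attr(x, "skipped"), collapse = ", "), "\n")
  NextMethod()
  invisible(x)
}

#' Joint adjustment of the score-trait association for a factor block
#'
#' Incremental adjusted R-squared of the score on the measured trait with
#' the full health-and-lifestyle block (and optionally a polygenic score)
#' in the base model — the "does the score survive joint adjustment"
#' analysis.
#'
#' @param y measured trait.
#' @param factors data.frame of adjustment factors (may be empty, in which
#'   case this reduces to the age-and-sex-only model).
#' @param score profile score.
#' @param covariates data.frame with `age` and `sex`.
#' @param pgs optional polygenic score added to the base model.
#' @return as [incremental_r2()].
#' @export
joint_adjustment_fit <- function(y, factors, score, covariates, pgs = NULL) {
  base <- data.frame(age = covariates$age, sex = as.numeric(covariates$sex))
  if (!is.null(factors) && ncol(factors) > 0)
    base <- cbind(base, factors[, setdiff(names(factors), "id"), drop = FALSE])
  if (!is.null(pgs)) base$pgs <- pgs
  incremental_r2(y, base, score)
}
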