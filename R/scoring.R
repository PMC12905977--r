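#' Marker weights for profile scoring
#'
#' Bundles posterior-mean marker effects with the training-cohort
#' phenotype anchors needed to place scores on the cm scale. Usually
#' constructed from a fitted [fit_bayesr()] object.
#'
#' @param x a `bayesr` fit, or a named numeric vector of weights.
#' @param set marker set to take weights from when `x` is a fit.
#' @param train_pheno_mean,train_pheno_sd phenotype mean and SD (cm) in the
#'   training cohort; required by [rescale_to_cm()].
#' @return object of class `weight_set`: `marker_ids`, `weights`, `source`,
#'   `train_pheno_mean`, `train_pheno_sd`.
#' @export
weight_set <- function(x, set = "dnam", train_pheno_mean = NA_real_,
                       train_pheno_sd = NA_real_) {
  if (inherits(x, "bayesr")) {
    w <- x$beta_mean[[set]]
    if (is.null(w)) stop("fit has no marker set: ", set)
    src <- paste0("bayesr:", set)
  } else {
    w <- x
    src <- "user"
  }
  if (is.null(names(w))) stop("weights must be named by marker id")
  if (anyDuplicated(names(w))) stop("duplicate marker ids in weights")
  if (any(!is.finite(w))) stop("non-finite weights")
  structure(list(marker_ids = names(w), weights = unname(w), source = src,
                 train_pheno_mean = train_pheno_mean,
                 train_pheno_sd = train_pheno_sd),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("Weight set (%s): %d markers, %d non-zero\n", x$source,
              length(x$weights), sum(x$weights != 0)))
  if (is.finite(x$train_pheno_mean))
    cat(sprintf("  training anchors: mean %.1f cm, SD %.1f cm\n",
                x$train_pheno_mean, x$train_pheno_sd))
  invisible(x)
}

#' Compute a methylation (or polygenic) profile score
#'
#' `score_i = sum_j w_j z_ij` over the intersection of weight markers and
#' the columns of the target matrix; markers absent from the target are
#' skipped and counted.
#'
#' @param weights a [weight_set()].
#' @param markers a `resid_matrix` (target markers, residualized and
#'   standardized with the same covariate specification as in training) or
#'   a plain matrix with column names.
#' @return numeric score vector with attributes `n_used` and `n_missing`.
#' @export
compute_mps <- function(weights, markers) {
  stopifnot(inherits(weights, "weight_set"))
  v <- if (inherits(markers, "resid_matrix")) markers$values else markers
  stopifnot(is.matrix(v), !is.null(colnames(v)))
  common <- intersect(weights$marker_ids, colnames(v))
  if (length(common) == 0) {
    stop("no overlap between weight markers and target matrix; first missing: ",
         paste(utils::head(weights$marker_ids, 10), collapse = ", "))
  }
  w <- weights$weights[match(common, weights$marker_ids)]
  score <- as.vector(v[, common, drop = FALSE] %*% w)
  attr(score, "n_used") <- length(common)
  attr(score, "n_missing") <- length(weights$marker_ids) - length(common)
  score
}

#' Rescale a raw profile score to the cm scale
#'
#' Z-scores the raw score in the target sample and re-anchors it to the
#' training-cohort phenotype mean and SD, so the score reads in cm. With
#' `anchors = "target"` the target phenotype's own mean/SD are used
#' instead.
#'
#' @param raw numeric raw score from [compute_mps()].
#' @param weights a [weight_set()] carrying the training anchors.
#' @param anchors `"train"` (default) or `"target"`.
#' @param target_pheno target phenotype, required for `anchors = "target"`.
#' @return numeric cm-scale score.
#' @export
rescale_to_cm <- function(raw, weights, anchors = c("train", "target"),
                          target_pheno = NULL) {
  anchors <- match.arg(anchors)
  s <- stats::sd(raw)
  if (s == 0) stop("raw score has zero variance")
  z <- (raw - mean(raw)) / s
  if (anchors == "train") {
    if (!is.finite(weights$train_pheno_mean) || !is.finite(weights$train_pheno_sd))
      stop("training anchors missing from weight set")
    z * weights$train_pheno_sd + weights$train_pheno_mean
  } else {
    if (is.null(target_pheno)) stop("target_pheno required for target anchors")
    z * stats::sd(target_pheno) + mean(target_pheno)
  }
}

#' Incremental adjusted R-squared of a score over base covariates
#'
#' Fits `y ~ base` and `y ~ base + score` by OLS (age and sex are always
#' included in the base model) and returns the difference in adjusted
#' R-squared plus the Wald p-value of the score coefficient in the full
#' model. Adjusted R-squared may be negative; the increment may be
#' negative for an uninformative score.
#'
#' @param y numeric phenotype.
#' @param base_covariates data.frame with at least `age` and `sex`;
#'   additional columns are included as given.
#' @param score numeric score vector.
#' @return list: `incremental_adj_r2`, `p_value` (score coefficient),
#'   `adj_r2_base`, `adj_r2_full`, `collinear` flag.
#' @export
incremental_r2 <- function(y, base_covariates, score) {
  stopifnot(all(c("age", "sex") %in% names(base_covariates)),
            length(y) == nrow(base_covariates), length(score) == length(y))
  cols <- setdiff(names(base_covariates), "id")
  df <- base_covariates[, cols, drop = FALSE]
  df$.y <- y
  base <- stats::lm(stats::reformulate(cols, response = ".y"), data = df)
  df$.score <- score
  full <- stats::lm(stats::reformulate(c(cols, ".score"), response = ".y"),
                    data = df)
  cf <- summary(full)$coefficients
  if (!".score" %in% rownames(cf) || is.na(stats::coef(full)[".score"])) {
    return(list(incremental_adj_r2 = 0, p_value = NA_real_,
                adj_r2_base = summary(base)$adj.r.squared,
                adj_r2_full = summary(base)$adj.r.squared,
                collinear = TRUE))
  }
  list(incremental_adj_r2 = summary(full)$adj.r.squared -
         summary(base)$adj.r.squared,
       p_value = cf[".score", 4],
       adj_r2_base = summary(base)$adj.r.squared,
       adj_r2_full = summary(full)$adj.r.squared,
       collinear = FALSE)
}

#' Phenotype contrast between top and bottom score deciles
#'
#' Splits individuals into deciles of the score by empirical quantile rank
#' (ties broken by stable index order) and returns the mean phenotype
#' difference between the top and bottom decile with a Welch t-test
#' p-value.
#'
#' @param score numeric score.
#' @param y numeric phenotype, same length.
#' @return list: `diff` (mean top minus bottom, phenotype units),
#'   `p_value`, `n_per_decile`.
#' @export
decile_contrast <- function(score, y) {
  n <- length(score)
  stopifnot(length(y) == n)
  if (n < 20) stop("n >= 20 required for a decile contrast")
  rk <- order(order(score))                  # stable ranks, ties by index
  dec <- ceiling(rk * 10 / n)
  top <- y[dec == 10]
  bot <- y[dec == 1]
  tt <- stats::t.test(top, bot)
  list(diff = mean(top) - mean(bot), p_value = tt$p.value,
       n_per_decile = c(bottom = length(bot), top = length(top)))
}

#' Out-of-sample score evaluation report
#'
#' Convenience wrapper producing the standard evaluation block for a
#' profile score in a target cohort: raw and cm-scale scores, Pearson
#' correlation with the phenotype, incremental adjusted R-squared over the
#' base covariates, and the top-vs-bottom decile contrast.
#'
#' @param weights a [weight_set()].
#' @param markers target `resid_matrix`.
#' @param y target phenotype (cm).
#' @param covariates target covariate data.frame (age, sex, ...).
#' @return object of class `score_report`.
#' @export
score_report <- function(weights, markers, y, covariates) {
  raw <- compute_mps(weights, markers)
  cm <- rescale_to_cm(raw, weights)
  ct <- stats::cor.test(raw, y)
  inc <- incremental_r2(y, covariates[, c("age", "sex")], cm)
  dc <- decile_contrast(cm, y)
  structure(list(score_raw = raw, score_cm = cm,
                 pearson_r = unname(ct$estimate), r_pvalue = ct$p.value,
                 incremental_adj_r2 = inc$incremental_adj_r2,
                 score_pvalue = inc$p_value,
                 decile_diff_cm = dc$diff, decile_pvalue = dc$p_value,
                 n = length(y), n_markers_used = attr(raw, "n_used")),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("Profile score evaluation (n = %d, %d markers)\n",
              x$n, x$n_markers_used))
  cat(sprintf("  Pearson r with phenotype: %.3f (p = %.2g)\n",
              x$pearson_r, x$r_pvalue))
  cat(sprintf("  incremental adjusted R2 over age + sex: %.4f (p = %.2g)\n",
              x$incremental_adj_r2, x$score_pvalue))
  cat(sprintf("  top - bottom decile: %.2f cm (p = %.2g)\n",
              x$decile_diff_cm, x$decile_pvalue))
  invisible(x)
}
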