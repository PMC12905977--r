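#' Residualize a phenotype on age, age squared, sex and optional covariates
#'
#' Regresses the trait on an intercept, age, age squared and sex by OLS
#' (plus any extra columns, e.g. a polygenic score when the analysis is to
#' be conditioned on one as a fixed effect) and returns the residuals.
#'
#' @param phenotype numeric vector, no missing values.
#' @param covariates data.frame containing at least `age` and `sex`.
#' @param extra character vector of additional covariate column names in
#'   `covariates` to include as fixed effects.
#' @return numeric residual vector, orthogonal to the design.
#' @export
residualize_phenotype <- function(phenotype, covariates, extra = NULL) {
  if (anyNA(phenotype)) stop("phenotype contains missing values")
  stopifnot(all(c("age", "sex") %in% names(covariates)),
            nrow(covariates) == length(phenotype))
  if (!all(extra %in% names(covariates)))
    stop("extra covariate(s) not found: ",
         paste(setdiff(extra, names(covariates)), collapse = ", "))
  df <- data.frame(age = covariates$age, age2 = covariates$age^2,
                   sex = as.numeric(covariates$sex))
  if (length(extra)) df <- cbind(df, covariates[, extra, drop = FALSE])
  X <- stats::model.matrix(stats::reformulate(names(df)), df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  as.vector(qr.resid(qx, phenotype))
}

#' Residualize and standardize a marker matrix
#'
#' Replaces each marker column by its OLS residual on the covariate design
#' and rescales to unit variance. Columns with (residual) variance
#' numerically zero are dropped and recorded, never imputed. With
#' `covariates = NULL` the result is plain column z-scores, the convention
#' for genotype dosages.
#'
#' @param m numeric matrix, individuals x markers, with column names.
#' @param covariates data.frame of covariates to regress out of every
#'   column (factors expanded to indicators), or `NULL` for
#'   standardization only.
#' @param cols character vector naming the covariate columns to use;
#'   defaults to all columns except `id`.
#' @return An object of class `resid_matrix`: list with `values` (n x p
#'   matrix, columns mean 0 variance 1), `marker_ids`, `covariate_spec`,
#'   and `dropped` (ids of zero-variance columns removed).
#' @export
residualize_markers <- function(m, covariates = NULL, cols = NULL) {
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  if (anyNA(m)) stop("marker matrix contains missing values; impute upstream")
  spec <- "(standardize only)"
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == nrow(m))
    if (is.null(cols)) cols <- setdiff(names(covariates), "id")
    spec <- paste(cols, collapse = " + ")
    X <- stats::model.matrix(stats::reformulate(cols),
                             data = covariates[, cols, drop = FALSE])
    m <- qr.resid(qr(X), m)
  } else {
    m <- sweep(m, 2, colMeans(m), "-")
  }
  v <- apply(m, 2, stats::var)
  keep <- v > 1e-12
  dropped <- colnames(m)[!keep]
  if (length(dropped) > 0)
    warning(length(dropped), " zero-variance column(s) dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  m <- m[, keep, drop = FALSE]
  m <- sweep(m, 2, colMeans(m), "-")         # exact re-centering
  m <- sweep(m, 2, sqrt(apply(m, 2, stats::var)), "/")
  out <- list(values = m, marker_ids = colnames(m),
              covariate_spec = spec, dropped = dropped)
  class(out) <- "resid_matrix"
  out
}

#' @export
print.resid_matrix <- function(x, ...) {
  cat(sprintf("Residualized marker matrix: %d individuals x %d markers\n",
              nrow(x$values), ncol(x$values)))
  cat("  adjusted for:", x$covariate_spec, "\n")
  if (length(x$dropped)) cat("  dropped:", length(x$dropped), "columns\n")
  invisible(x)
}

#' Standardize genotype dosages by allele frequency
#'
#' Centers each SNP column by twice its (estimated) allele frequency and
#' scales by `sqrt(2 p (1 - p))` — the standardization underlying the
#' conventional genomic relationship matrix. Monomorphic SNPs are dropped
#' with a warning.
#'
#' @param g dosage matrix (0-2), individuals x SNPs, with column names.
#' @return a `resid_matrix` whose columns are allele-frequency-standardized
#'   dosages (mean 0; variance 1 only in Hardy-Weinberg expectation).
#' @export
standardize_genotypes <- function(g) {
  stopifnot(is.matrix(g), !is.null(colnames(g)))
  p <- colMeans(g) / 2
  keep <- p > 0 & p < 1
  dropped <- colnames(g)[!keep]
  if (length(dropped) > 0)
    warning(length(dropped), " monomorphic SNP(s) dropped")
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  z <- sweep(sweep(g, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  out <- list(values = z, marker_ids = colnames(z),
              covariate_spec = "(allele-frequency standardization)",
              dropped = dropped)
  class(out) <- "resid_matrix"
  out
}

#' Compute an omics or genomic relationship matrix
#'
#' Returns `(1/p) Z Z'` on the standardized matrix: the omics relationship
#' matrix (ORM) for residualized probes, the genomic relationship matrix
#' (GRM) for allele-frequency-standardized dosages. Accumulates over marker
#' blocks so the n x p matrix never needs to be duplicated.
#'
#' @param z a `resid_matrix` (or plain standardized matrix).
#' @param kind `"ORM"` or `"GRM"` tag.
#' @param chunk_size markers per accumulation block.
#' @return object of class `rel_matrix`: list with `values` (n x n,
#'   symmetric), `kind`, `n_markers`.
#' @export
relationship_matrix <- function(z, kind = c("ORM", "GRM"), chunk_size = 2000L) {
  kind <- match.arg(kind)
  v <- if (inherits(z, "resid_matrix")) z$values else z
  stopifnot(is.matrix(v), ncol(v) >= 2)
  n <- nrow(v)
  p <- ncol(v)
  K <- matrix(0, n, n)
  for (start in seq(1L, p, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, p)
    zi <- v[, idx, drop = FALSE]
    K <- K + tcrossprod(zi)
  }
  K <- K / p
  K <- (K + t(K)) / 2
  rownames(K) <- colnames(K) <- rownames(v)
  out <- list(values = K, kind = kind, n_markers = p)
  class(out) <- "rel_matrix"
  out
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("%s: %d x %d from %d markers; mean diagonal %.3f\n",
              x$kind, nrow(x$values), ncol(x$values), x$n_markers,
              mean(diag(x$values))))
  invisible(x)
}

#' Greedy filter to an unrelated individual set
#'
#' While any off-diagonal relatedness is at or above the threshold, removes
#' the individual involved in the most above-threshold pairs (on ties the
#' lower-indexed individual is kept; the highest-indexed candidate is
#' removed). The surviving index set induces a submatrix
#' with all off-diagonal entries below the threshold.
#'
#' @param rel a `rel_matrix` or symmetric matrix.
#' @param threshold relatedness cutoff (conventionally 0.05).
#' @return integer vector of kept row indices, in original order.
#' @export
filter_unrelated <- function(rel, threshold = 0.05) {
  if (threshold <= 0) stop("threshold must be positive")
  K <- if (inherits(rel, "rel_matrix")) rel$values else rel
  stopifnot(isSymmetric(unname(K), tol = 1e-8))
  n <- nrow(K)
  A <- (K >= threshold)
  diag(A) <- FALSE
  alive <- rep(TRUE, n)
  deg <- rowSums(A)
  while (any(deg[alive] > 0)) {
    cand <- which(alive & deg == max(deg[alive]))
    drop <- cand[length(cand)]            # tie: keep the lower index
    alive[drop] <- FALSE
    A[drop, ] <- FALSE
    A[, drop] <- FALSE
    deg <- rowSums(A)
  }
  which(alive)
}

#' Mean-impute missing marker values
#'
#' Optional helper for real-data ingestion: replaces missing entries of a
#' marker matrix by their column means. The core fits deliberately reject
#' missing data, so imputation is always an explicit, separate step.
#'
#' @param m numeric matrix with possible `NA`s.
#' @return matrix of the same shape with no missing values; attribute
#'   `n_imputed` records how many cells were filled.
#' @export
impute_mean <- function(m) {
  stopifnot(is.matrix(m))
  na <- is.na(m)
  if (any(colSums(!na) == 0)) stop("column(s) entirely missing")
  if (any(na)) {
    mu <- unname(colMeans(m, na.rm = TRUE))
    idx <- which(na, arr.ind = TRUE)
    m[na] <- mu[idx[, 2]]
  }
  attr(m, "n_imputed") <- sum(na)
  m
}
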