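#' REML variance components on relationship matrices
#'
#' Estimates the fractions of phenotypic variance attached to one or more
#' relationship matrices (ORM and/or GRM) under the infinitesimal model
#' `y ~ N(Xb, sum_k sigma2_k K_k + sigma2_e I)`, by average-information
#' REML with EM fallback steps whenever the AI update proposes an
#' out-of-bounds point. Standard errors come from the inverse AI matrix at
#' convergence, mapped to the fraction scale by the delta method.
#'
#' @param y numeric residualized phenotype.
#' @param rels a `rel_matrix`, or a (preferably named) list of them.
#' @param covariates optional fixed-effect covariates absorbed via the
#'   REML projection: a data.frame (expanded with an intercept) or a
#'   design matrix used as-is.
#' @param max_iter maximum AI/EM iterations.
#' @param tol_ll,tol_par convergence tolerances on the restricted
#'   log-likelihood change and parameter change.
#' @return object of class `oreml`: `var_components` (fractions of
#'   phenotypic variance per matrix + residual), `se`, `ci95`
#'   (estimate +/- 1.96 SE, clamped to \[0,1\] with `boundary` flags),
#'   `sigma2` (absolute components), `loglik`, `n_iter_used`, `converged`.
#' @export
fit_reml <- function(y, rels, covariates = NULL, max_iter = 100,
                     tol_ll = 1e-8, tol_par = 1e-6) {
  if (inherits(rels, "rel_matrix")) rels <- list(rels)
  K_list <- lapply(rels, function(r) if (inherits(r, "rel_matrix")) r$values else r)
  m <- length(K_list)
  nm <- names(rels) %||% NULL
  if (is.null(nm) || any(nm == ""))
    nm <- vapply(seq_len(m), function(i) {
      if (inherits(rels[[i]], "rel_matrix")) rels[[i]]$kind else paste0("K", i)
    }, character(1))
  nm <- make.unique(tolower(nm))
  n <- length(y)
  for (K in K_list) stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n)

  ## identifiability: a relationship matrix proportional to I is aliased
  ## with the residual
  for (i in seq_len(m)) {
    K <- K_list[[i]]
    off <- K - diag(mean(diag(K)), n)
    if (sqrt(sum(off^2)) / n < 1e-8)
      stop("relationship matrix '", nm[i],
           "' is numerically proportional to the identity; ",
           "its variance component is not identifiable from the residual")
  }

  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n)
    if (is.matrix(covariates)) {
      X <- covariates                       # design used as-is (no intercept)
    } else {
      cols <- setdiff(names(covariates), "id")
      X <- stats::model.matrix(stats::reformulate(cols),
                               data = covariates[, cols, drop = FALSE])
    }
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient fixed-effect design")

  vary <- stats::var(y)
  lower <- 1e-8 * vary
  sig <- rep(vary / (m + 1), m + 1)          # components..., residual
  Ks <- c(K_list, list(diag(n)))

  ll_old <- -Inf
  converged <- FALSE
  used <- 0
  AI <- NULL
  for (iter in seq_len(max_iter)) {
    used <- iter
    V <- diag(sig[m + 1], n)
    for (k in seq_len(m)) V <- V + sig[k] * Ks[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {                        # shouldn't occur with sig > 0
      sig <- pmax(sig, lower) * 1.1
      next
    }
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    P <- Vi - t(XtVi) %*% solve(XtViX, XtVi)
    Py <- as.vector(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                  determinant(XtViX, logarithm = TRUE)$modulus[1] +
                  sum(y * Py))
    t1 <- lapply(Ks, function(K) as.vector(K %*% Py))   # K_k P y
    score <- vapply(seq_len(m + 1), function(k) {
      -0.5 * (sum(P * Ks[[k]]) - sum(Py * t1[[k]]))
    }, numeric(1))
    Pt1 <- lapply(t1, function(v) as.vector(P %*% v))
    AI <- matrix(0, m + 1, m + 1)
    for (k in seq_len(m + 1))
      for (l in k:(m + 1))
        AI[k, l] <- AI[l, k] <- 0.5 * sum(t1[[k]] * Pt1[[l]])

    delta <- tryCatch(solve(AI, score), error = function(e) NULL)
    prop <- if (is.null(delta)) rep(-1, m + 1) else sig + delta
    if (any(prop < 0)) {
      ## EM fallback step (always within bounds)
      prop <- vapply(seq_len(m + 1), function(k) {
        sig[k] + sig[k]^2 * (sum(Py * t1[[k]]) - sum(P * Ks[[k]])) / n
      }, numeric(1))
      prop <- pmax(prop, lower)
    }
    dpar <- max(abs(prop - sig))
    sig <- pmax(prop, lower)
    if (iter > 1 && (abs(ll - ll_old) < tol_ll || dpar < tol_par)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!converged)
    warning("AI-REML did not converge in ", max_iter, " iterations")

  tot <- sum(sig)
  frac <- sig / tot
  Sigma <- tryCatch(solve(AI), error = function(e) matrix(NA, m + 1, m + 1))
  ## delta method: f_k = sig_k / sum(sig)
  se_frac <- vapply(seq_len(m + 1), function(k) {
    g <- -sig[k] / tot^2 * rep(1, m + 1)
    g[k] <- g[k] + 1 / tot
    sqrt(max(0, as.numeric(t(g) %*% Sigma %*% g)))
  }, numeric(1))
  boundary <- sig <= lower * 1.01
  ci <- rbind(lower = frac - 1.96 * se_frac, upper = frac + 1.96 * se_frac)
  clamped <- pmin(pmax(ci, 0), 1)
  names(frac) <- names(se_frac) <- c(nm, "residual")
  colnames(ci) <- colnames(clamped) <- c(nm, "residual")
  out <- list(var_components = frac, se = se_frac, ci95 = clamped,
              ci95_unclamped = ci, sigma2 = stats::setNames(sig, c(nm, "residual")),
              boundary = stats::setNames(boundary, c(nm, "residual")),
              loglik = ll_old, n_iter_used = used, converged = converged,
              n = n, call = match.call())
  class(out) <- "oreml"
  out
}

#' @export
print.oreml <- function(x, ...) {
  cat(sprintf("REML variance components (n = %d, %s in %d iterations)\n",
              x$n, if (x$converged) "converged" else "NOT converged",
              x$n_iter_used))
  for (nm in names(x$var_components)) {
    cat(sprintf("  %-9s %5.1f%%  (SE %.1f%%, 95%% CI %.1f-%.1f%%)%s\n", nm,
                100 * x$var_components[nm], 100 * x$se[nm],
                100 * x$ci95["lower", nm], 100 * x$ci95["upper", nm],
                if (x$boundary[nm]) "  [boundary]" else ""))
  }
  cat(sprintf("  restricted log-likelihood: %.3f\n", x$loglik))
  invisible(x)
}

#' @export
coef.oreml <- function(object, ...) object$var_components

## Restricted log-likelihood of y ~ N(Xb, V); shared by the bivariate fit.
.reml_ll <- function(y, X, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  P <- tryCatch(Vi - t(XtVi) %*% solve(XtViX, XtVi),
                error = function(e) NULL)
  if (is.null(P)) return(-Inf)
  -0.5 * (2 * sum(log(diag(ch))) +
          determinant(XtViX, logarithm = TRUE)$modulus[1] +
          sum(y * (P %*% y)))
}

#' Bivariate cross-sex variance decomposition
#'
#' Treats the trait in males and in females as two traits observed on
#' disjoint individuals and models the cross-sex covariance of the
#' omics-associated effect as `r * sigma_1 * sigma_2 * K` on the cross
#' block of the relationship matrix. Estimates per-group variance
#' fractions, the cross-group effect correlation `r` (optimized on the
#' atanh scale so it stays in (-1, 1)) and a likelihood-ratio test of
#' `r = 1` (boundary null; the p-value uses the half-chi-square mixture).
#'
#' @param y numeric residualized phenotype.
#' @param sex binary vector (two distinct values; the lower value defines
#'   group 1).
#' @param rel a `rel_matrix` over all individuals.
#' @return object of class `bivar_oreml`: `var_frac_group1`,
#'   `var_frac_group2`, `r_corr`, `se_r`, `lrt_r_eq_1`, `p_r_eq_1`,
#'   `loglik`, `groups`.
#' @export
fit_bivariate_sex <- function(y, sex, rel) {
  K <- if (inherits(rel, "rel_matrix")) rel$values else rel
  n <- length(y)
  stopifnot(nrow(K) == n, length(sex) == n)
  lev <- sort(unique(sex))
  if (length(lev) != 2) stop("both sexes must be present")
  i1 <- which(sex == lev[1])
  i2 <- which(sex == lev[2])
  if (min(length(i1), length(i2)) < 50)
    stop("need >= 50 individuals per sex")
  idx <- c(i1, i2)
  yo <- y[idx]
  Ko <- K[idx, idx]
  n1 <- length(i1)
  g <- rep(1:2, c(n1, length(i2)))
  X <- cbind(as.numeric(g == 1), as.numeric(g == 2))
  B11 <- outer(g == 1, g == 1)
  B22 <- outer(g == 2, g == 2)
  B12 <- outer(g == 1, g == 2) | outer(g == 2, g == 1)

  vary <- stats::var(yo)
  build_V <- function(s1, s2, r, e1, e2) {
    G <- Ko * (B11 * s1 + B22 * s2 + B12 * r * sqrt(s1 * s2))
    G + diag(ifelse(g == 1, e1, e2))
  }
  nll <- function(par, r_fixed = NULL) {
    s1 <- exp(par[1]); s2 <- exp(par[2])
    r <- if (is.null(r_fixed)) tanh(par[3]) else r_fixed
    k <- if (is.null(r_fixed)) 3 else 2
    e1 <- exp(par[k + 1]); e2 <- exp(par[k + 2])
    -.reml_ll(yo, X, build_V(s1, s2, r, e1, e2))
  }
  start <- log(c(vary / 2, vary / 2))
  ## the restricted likelihood can be flat or multimodal in r when a group
  ## variance is small; start from several correlations and keep the best
  tmax <- atanh(0.99)           # |r| capped at 0.99: beyond, the surface is
                                # flat in atanh(r) and the SE degenerates
  fits <- lapply(c(0, 0.5, -0.5), function(r0) {
    stats::optim(c(start, atanh(r0), start), nll,
                 method = "L-BFGS-B",
                 lower = c(rep(-Inf, 2), -tmax, rep(-Inf, 2)),
                 upper = c(rep(Inf, 2), tmax, rep(Inf, 2)),
                 hessian = TRUE,
                 control = list(maxit = 200, factr = 1e4))
  })
  fit_free <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  fit_r1 <- stats::optim(c(start, start), nll, r_fixed = 1,
                         method = "BFGS",
                         control = list(maxit = 200, reltol = 1e-10))
  s1 <- exp(fit_free$par[1]); s2 <- exp(fit_free$par[2])
  r <- tanh(fit_free$par[3])
  e1 <- exp(fit_free$par[4]); e2 <- exp(fit_free$par[5])
  se_t <- tryCatch(sqrt(solve(fit_free$hessian)[3, 3]),
                   error = function(e) NA_real_)
  se_r <- (1 - r^2) * se_t
  lrt <- max(0, 2 * (fit_r1$value - fit_free$value))
  p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  out <- list(var_frac_group1 = s1 / (s1 + e1),
              var_frac_group2 = s2 / (s2 + e2),
              r_corr = r, se_r = se_r,
              lrt_r_eq_1 = lrt, p_r_eq_1 = p,
              loglik = -fit_free$value,
              groups = stats::setNames(c(length(i1), length(i2)),
                                       as.character(lev)),
              call = match.call())
  class(out) <- "bivar_oreml"
  out
}

#' @export
print.bivar_oreml <- function(x, ...) {
  cat("Bivariate cross-sex variance decomposition\n")
  cat(sprintf("  group 1 (%s, n = %d): %5.1f%% of variance\n",
              names(x$groups)[1], x$groups[1], 100 * x$var_frac_group1))
  cat(sprintf("  group 2 (%s, n = %d): %5.1f%% of variance\n",
              names(x$groups)[2], x$groups[2], 100 * x$var_frac_group2))
  cat(sprintf("  cross-sex effect correlation r = %.2f (SE %.2f), p[r=1] = %.3f\n",
              x$r_corr, x$se_r, x$p_r_eq_1))
  invisible(x)
}
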