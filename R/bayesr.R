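#' Spike-plus-mixture prior for whole-genome regression
#'
#' Defines the effect-size prior used by [fit_bayesr()]: each marker's
#' effect is zero (the spike) or drawn from one of a small number of normal
#' components whose variances are fixed fractions of the phenotypic
#' variance. The defaults 1e-4, 1e-3 and 1e-2 define "small", "medium" and
#' "large" classes capturing 0.01%, 0.1% and 1% of phenotypic variance per
#' marker.
#'
#' @param component_fracs strictly increasing variances of the non-spike
#'   components, as fractions of phenotypic variance, all in (0, 1).
#' @param dirichlet_alpha concentration of the symmetric Dirichlet prior on
#'   the mixture proportions (spike included).
#' @param resid_df,resid_scale scaled-inverse-chi-square hyperparameters
#'   for the residual variance; `resid_scale = NULL` defaults to
#'   `0.5 * Var(y)` at fit time.
#' @param fix_pi optional fixed mixture proportions (length
#'   `length(component_fracs) + 1`, spike first); disables the Dirichlet
#'   update. Used for calibration studies against closed-form posteriors.
#' @return object of class `mixture_prior`.
#' @export
mixture_prior <- function(component_fracs = c(1e-4, 1e-3, 1e-2),
                          dirichlet_alpha = 1,
                          resid_df = 4, resid_scale = NULL,
                          fix_pi = NULL) {
  stopifnot(length(component_fracs) >= 1,
            all(component_fracs > 0), all(component_fracs < 1),
            !is.unsorted(component_fracs, strictly = TRUE),
            dirichlet_alpha > 0, resid_df > 0)
  if (!is.null(fix_pi)) {
    stopifnot(length(fix_pi) == length(component_fracs) + 1,
              all(fix_pi >= 0), abs(sum(fix_pi) - 1) < 1e-8)
  }
  structure(list(component_fracs = component_fracs,
                 dirichlet_alpha = dirichlet_alpha,
                 resid_df = resid_df, resid_scale = resid_scale,
                 fix_pi = fix_pi),
            class = "mixture_prior")
}

#' MCMC settings for [fit_bayesr()]
#'
#' @param n_iter total Gibbs sweeps per chain.
#' @param burn_in sweeps discarded before retention (`< n_iter`).
#' @param thin retain every `thin`-th post-burn-in sweep.
#' @param n_chains independent chains (seeds `seed`, `seed + 1`, ...);
#'   retained draws are pooled.
#' @param seed integer seed for the first chain.
#' @return object of class `mcmc_spec`.
#' @export
mcmc_spec <- function(n_iter = 10000, burn_in = 5000, thin = 5,
                      n_chains = 2, seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed)),
            class = "mcmc_spec")
}

.as_marker_set <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "resid_matrix")) return(x)
  if (is.matrix(x))
    return(list(values = x,
                marker_ids = colnames(x) %||% paste0(what, "_", seq_len(ncol(x)))))
  stop(what, " must be a resid_matrix or numeric matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bayesian variance partitioning over one or two marker sets
#'
#' Fits the joint penalised regression of a (residualized) trait on all
#' markers of one or two column-standardized sets — typically DNA
#' methylation probes and SNP dosages — by single-site Gibbs sampling under
#' a spike-plus-mixture prior ([mixture_prior()]). Per retained draw the
#' realized linear predictor of each set is formed and its share of
#' phenotypic variance recorded; the per-draw decomposition allocates the
#' covariance between sets so that set fractions plus the residual fraction
#' sum to one exactly.
#'
#' The trait is standardized to unit variance internally; reported variance
#' fractions are invariant to this, and posterior-mean effects are returned
#' on the scale of the supplied trait.
#'
#' @param y numeric residualized phenotype, length n >= 50.
#' @param dnam,snp marker sets (a `resid_matrix` from
#'   [residualize_markers()]/[standardize_genotypes()], or a plain
#'   column-standardized matrix). Supply one for a marginal fit, both for
#'   the joint fit.
#' @param prior a [mixture_prior()].
#' @param mcmc an [mcmc_spec()].
#' @param fix_resid_var optional known residual variance (on the internal
#'   unit-variance scale of `y`); disables the residual-variance update.
#' @return object of class `bayesr`: list with `var_frac` (posterior-mean
#'   fraction per set + residual), `cri95` (equal-tailed 95% credible
#'   intervals), `pip`, `beta_mean` (named, per set, on the scale of `y`),
#'   `class_counts`, `class_var_share`, `pi_mean`, `samples` (retained
#'   per-draw fractions), `sigma2e_draws`, `sets`, `mcmc`, `prior`.
#' @export
fit_bayesr <- function(y, dnam = NULL, snp = NULL,
                       prior = mixture_prior(), mcmc = mcmc_spec(),
                       fix_resid_var = NULL) {
  stopifnot(inherits(prior, "mixture_prior"), inherits(mcmc, "mcmc_spec"))
  sets <- list(dnam = .as_marker_set(dnam, "dnam"),
               snp = .as_marker_set(snp, "snp"))
  sets <- sets[!vapply(sets, is.null, logical(1))]
  if (length(sets) == 0) stop("supply at least one marker set")
  n <- length(y)
  if (n < 50) stop("n >= 50 required")
  if (anyNA(y)) stop("y contains missing values")
  for (nm in names(sets)) {
    v <- sets[[nm]]$values
    stopifnot(nrow(v) == n)
    cv <- apply(v, 2, stats::var)
    if (max(abs(cv - 1)) > 1e-3)
      stop("marker set '", nm, "' is not column-standardized ",
           "(max |var - 1| = ", format(max(abs(cv - 1))), ")")
  }
  sdy <- stats::sd(y)
  if (sdy == 0) stop("y has zero variance")
  ys <- as.vector(scale(y))
  resid_scale <- prior$resid_scale %||% 0.5   # Var(ys) = 1

  Zlist <- lapply(sets, `[[`, "values")
  K <- length(prior$component_fracs)
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch - 1L)
    chains[[ch]] <- .bayesr_gibbs(
      ys, unname(Zlist), prior$component_fracs, prior$dirichlet_alpha,
      prior$resid_df, resid_scale,
      mcmc$n_iter, mcmc$burn_in, mcmc$thin,
      if (is.null(fix_resid_var)) -1 else fix_resid_var,
      prior$fix_pi, 1.0)
  }

  S <- length(sets)
  frac_draws <- do.call(rbind, lapply(chains, `[[`, "frac_draws"))
  colnames(frac_draws) <- c(names(sets), "residual")
  sigma2e_draws <- unlist(lapply(chains, `[[`, "sigma2e_draws"))
  n_draws <- nrow(frac_draws)
  avg <- function(field) Reduce(`+`, lapply(chains, `[[`, field)) / length(chains)
  pip <- beta_mean <- pi_mean <- stats::setNames(vector("list", S), names(sets))
  for (s in seq_len(S)) {
    ids <- sets[[s]]$marker_ids
    pip[[s]] <- stats::setNames(avg_list(chains, "pip", s), ids)
    beta_mean[[s]] <- stats::setNames(avg_list(chains, "beta_mean", s) * sdy, ids)
    pi_mean[[s]] <- avg_list(chains, "pi_mean", s)
  }
  class_counts <- avg("class_counts")
  class_shares <- avg("class_shares")
  dimnames(class_counts) <- dimnames(class_shares) <-
    list(names(sets), paste0("class_", seq_len(K)))

  var_frac <- colMeans(frac_draws)
  cri95 <- apply(frac_draws, 2, stats::quantile, probs = c(0.025, 0.975))
  out <- list(
    var_frac = var_frac, cri95 = cri95,
    pip = pip, beta_mean = beta_mean, pi_mean = pi_mean,
    class_counts = class_counts, class_var_share = class_shares,
    samples = frac_draws, sigma2e_draws = sigma2e_draws,
    n_draws = n_draws, sets = names(sets),
    marker_ids = lapply(sets, `[[`, "marker_ids"),
    y_sd = sdy, prior = prior, mcmc = mcmc, n = n,
    call = match.call()
  )
  class(out) <- "bayesr"
  out
}

avg_list <- function(chains, field, s) {
  as.vector(Reduce(`+`, lapply(chains, function(ch) ch[[field]][[s]]))) /
    length(chains)
}

#' @export
print.bayesr <- function(x, ...) {
  cat("Bayesian mixture variance partitioning (", x$n_draws,
      " retained draws, ", x$mcmc$n_chains, " chain(s))\n", sep = "")
  for (nm in names(x$var_frac)) {
    cat(sprintf("  %-9s %5.1f%%  (95%% CrI %.1f-%.1f%%)\n", nm,
                100 * x$var_frac[nm], 100 * x$cri95[1, nm],
                100 * x$cri95[2, nm]))
  }
  invisible(x)
}

#' @export
summary.bayesr <- function(object, ...) {
  hits <- lapply(object$sets, function(s) pip_hits(object, set = s))
  structure(list(fit = object, hits = hits,
                 architecture = architecture_table(object)),
            class = "summary.bayesr")
}

#' @export
print.summary.bayesr <- function(x, ...) {
  print(x$fit)
  cat("\nEffect-size-class architecture:\n")
  print(x$architecture, row.names = FALSE, digits = 3)
  for (s in seq_along(x$hits)) {
    h <- x$hits[[s]]
    cat(sprintf("\n%s markers with PIP > 0.95: %d\n",
                x$fit$sets[s], length(h)))
    if (length(h)) print(utils::head(h, 10))
  }
  invisible(x)
}

#' @export
coef.bayesr <- function(object, ...) object$beta_mean

#' Markers exceeding a posterior inclusion probability threshold
#'
#' @param fit a fitted [fit_bayesr()] object.
#' @param set marker set name (`"dnam"` or `"snp"`).
#' @param threshold PIP cutoff in (0, 1); the conventional discovery rule
#'   is PIP > 0.95.
#' @return named numeric vector of PIPs for markers above the threshold,
#'   sorted decreasing.
#' @export
pip_hits <- function(fit, set = fit$sets[1], threshold = 0.95) {
  stopifnot(inherits(fit, "bayesr"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  p <- fit$pip[[set]]
  if (is.null(p)) stop("unknown marker set: ", set)
  sort(p[p > threshold], decreasing = TRUE)
}

#' Effect-size-class architecture table
#'
#' Posterior expected number of markers per effect-size class and the mean
#' share of phenotypic variance attributable to each class, per marker set
#' — the decomposition of the polygenic signal into small, medium and
#' large effects.
#'
#' @param fit a fitted [fit_bayesr()] object.
#' @return data.frame with columns `set`, `class`, `component_frac`
#'   (the class's per-marker variance fraction), `expected_markers`,
#'   `var_share`.
#' @export
architecture_table <- function(fit) {
  stopifnot(inherits(fit, "bayesr"))
  K <- length(fit$prior$component_fracs)
  labs <- if (K == 3) c("small", "medium", "large") else paste0("class_", 1:K)
  do.call(rbind, lapply(seq_along(fit$sets), function(s) {
    data.frame(set = fit$sets[s], class = labs,
               component_frac = fit$prior$component_fracs,
               expected_markers = as.vector(fit$class_counts[s, ]),
               var_share = as.vector(fit$class_var_share[s, ]),
               row.names = NULL)
  }))
}
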