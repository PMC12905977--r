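// Single-site Gibbs sampler for multi-set Bayesian penalised regression
// with a spike at zero plus normal mixture components of fixed variance
// classes. Uses R's RNG throughout so results are reproducible from
// set.seed() on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sample_invchisq_scaled(double df, double scale) {
  // scaled inverse chi-square draw: df * scale / chisq(df)
  return df * scale / R::rchisq(df);
}

// Dirichlet draw via gammas, R RNG.
static arma::vec rdirichlet(const arma::vec& alpha) {
  arma::vec g(alpha.n_elem);
  for (arma::uword i = 0; i < alpha.n_elem; ++i)
    g[i] = R::rgamma(alpha[i], 1.0);
  double s = arma::accu(g);
  if (s <= 0) { g.fill(1.0 / g.n_elem); return g; }
  return g / s;
}

// [[Rcpp::export(name = ".bayesr_gibbs")]]
List bayesr_gibbs(const arma::vec& y,
                  const List& Zsets,
                  const arma::vec& comp_fracs,
                  double dirichlet_alpha,
                  double resid_df,
                  double resid_scale,
                  int n_iter, int burn_in, int thin,
                  double fix_resid_var,
                  Nullable<NumericVector> fix_pi_,
                  double sigma2P) {
  const int S = Zsets.size();
  const int K = comp_fracs.n_elem;          // non-spike components
  const int n = y.n_elem;
  const double vary = arma::var(y);

  std::vector<arma::mat> Z(S);
  std::vector<arma::vec> zz(S), beta(S);
  std::vector<arma::ivec> comp(S);
  std::vector<arma::vec> gset(S);
  std::vector<std::vector<arma::vec>> gclass(S);
  std::vector<arma::vec> pi(S);
  arma::ivec psize(S);
  int p_tot = 0;
  for (int s = 0; s < S; ++s) {
    Z[s] = as<arma::mat>(Zsets[s]);
    psize[s] = Z[s].n_cols;
    p_tot += psize[s];
    zz[s] = arma::sum(arma::square(Z[s]), 0).t();
    beta[s] = arma::zeros(psize[s]);
    comp[s] = arma::ivec(psize[s], arma::fill::zeros);
    gset[s] = arma::zeros(n);
    gclass[s].assign(K, arma::zeros(n));
    pi[s] = arma::vec(K + 1, arma::fill::value(1.0 / (K + 1)));
  }
  bool pi_fixed = fix_pi_.isNotNull();
  if (pi_fixed) {
    arma::vec fp = as<arma::vec>(fix_pi_.get());
    if ((int)fp.n_elem != K + 1) stop("fix_pi must have length n_components + 1");
    for (int s = 0; s < S; ++s) pi[s] = fp;
  }

  arma::vec s2k = comp_fracs * sigma2P;     // component effect variances
  double s2e = (fix_resid_var > 0) ? fix_resid_var : 0.5 * vary;
  arma::vec e = y;                          // residual (all beta start at 0)

  // global marker order: (set, index) pairs, reshuffled each sweep
  std::vector<std::pair<int,int>> order;
  order.reserve(p_tot);
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < psize[s]; ++j) order.emplace_back(s, j);

  const int n_draws = (n_iter - burn_in + thin - 1) / thin;
  arma::mat frac_draws(n_draws, S + 1, arma::fill::zeros);
  arma::vec s2e_draws(n_draws, arma::fill::zeros);
  std::vector<arma::vec> pip_sum(S), beta_sum(S);
  arma::mat count_sum(S, K, arma::fill::zeros);
  arma::mat share_sum(S, K, arma::fill::zeros);
  std::vector<arma::vec> pi_sum(S);
  for (int s = 0; s < S; ++s) {
    pip_sum[s] = arma::zeros(psize[s]);
    beta_sum[s] = arma::zeros(psize[s]);
    pi_sum[s] = arma::zeros(K + 1);
  }
  int stored = 0;

  arma::vec logp(K + 1), prob(K + 1);

  for (int iter = 1; iter <= n_iter; ++iter) {
    // Fisher-Yates shuffle with R's RNG
    for (int i = p_tot - 1; i > 0; --i) {
      int j = (int)(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }

    for (int idx = 0; idx < p_tot; ++idx) {
      int s = order[idx].first, j = order[idx].second;
      const double zzj = zz[s][j];
      if (zzj <= 0) continue;
      double bj = beta[s][j];
      int cj = comp[s][j];
      double rhs = arma::dot(Z[s].col(j), e) + zzj * bj;

      logp[0] = std::log(pi[s][0]);
      for (int k = 0; k < K; ++k) {
        double sk = s2k[k];
        logp[k + 1] = std::log(pi[s][k + 1])
          - 0.5 * std::log1p(zzj * sk / s2e)
          + 0.5 * rhs * rhs * sk / (s2e * (s2e + zzj * sk));
      }
      double m = logp.max();
      prob = arma::exp(logp - m);
      double tot = arma::accu(prob);
      double u = R::unif_rand() * tot, acc = 0.0;
      int cnew = K;                          // guard against fp round-off
      for (int k = 0; k <= K; ++k) { acc += prob[k]; if (u <= acc) { cnew = k; break; } }

      double bnew = 0.0;
      if (cnew > 0) {
        double sk = s2k[cnew - 1];
        double v = 1.0 / (zzj / s2e + 1.0 / sk);
        bnew = v * rhs / s2e + std::sqrt(v) * R::norm_rand();
      }
      if (bj != 0.0 || bnew != 0.0) {
        arma::vec zj = Z[s].col(j);
        e += zj * (bj - bnew);
        gset[s] += zj * (bnew - bj);
        if (cj > 0 && bj != 0.0) gclass[s][cj - 1] -= zj * bj;
        if (cnew > 0) gclass[s][cnew - 1] += zj * bnew;
      }
      beta[s][j] = bnew;
      comp[s][j] = cnew;
    }

    // mixture proportions
    if (!pi_fixed) {
      for (int s = 0; s < S; ++s) {
        arma::vec alpha(K + 1, arma::fill::value(dirichlet_alpha));
        for (int j = 0; j < psize[s]; ++j) alpha[comp[s][j]] += 1.0;
        pi[s] = rdirichlet(alpha);
      }
    }

    // residual variance
    if (fix_resid_var <= 0) {
      double ssq = arma::dot(e, e);
      s2e = sample_invchisq_scaled(resid_df + n,
             (resid_df * resid_scale + ssq) / (resid_df + n));
    }
    if (s2e > 10.0 * vary)
      stop("residual variance diverged (sigma2_e = %f > 10 Var(y)); check that inputs are standardized", s2e);

    if (iter > burn_in && ((iter - burn_in - 1) % thin == 0) && stored < n_draws) {
      arma::vec g_tot(n, arma::fill::zeros);
      for (int s = 0; s < S; ++s) g_tot += gset[s];
      double D = arma::var(g_tot) + s2e;
      double fsum = 0.0;
      for (int s = 0; s < S; ++s) {
        double f = arma::as_scalar(arma::cov(gset[s], g_tot)) / D;
        frac_draws(stored, s) = f;
        fsum += f;
        for (int k = 0; k < K; ++k) {
          int cnt = 0;
          for (int j = 0; j < psize[s]; ++j) if (comp[s][j] == k + 1) ++cnt;
          count_sum(s, k) += cnt;
          share_sum(s, k) += arma::as_scalar(arma::cov(gclass[s][k], g_tot)) / D;
        }
        for (int j = 0; j < psize[s]; ++j) {
          if (comp[s][j] > 0) pip_sum[s][j] += 1.0;
          beta_sum[s][j] += beta[s][j];
        }
        pi_sum[s] += pi[s];
      }
      frac_draws(stored, S) = s2e / D;       // residual fraction
      s2e_draws[stored] = s2e;
      ++stored;
    }
  }

  List pip(S), bmean(S), pimean(S);
  for (int s = 0; s < S; ++s) {
    pip[s] = NumericVector(wrap(pip_sum[s] / stored));
    bmean[s] = NumericVector(wrap(beta_sum[s] / stored));
    pimean[s] = NumericVector(wrap(pi_sum[s] / stored));
  }
  return List::create(
    _["frac_draws"] = frac_draws.rows(0, stored - 1),
    _["sigma2e_draws"] = s2e_draws.head(stored),
    _["pip"] = pip,
    _["beta_mean"] = bmean,
    _["pi_mean"] = pimean,
    _["class_counts"] = count_sum / stored,
    _["class_shares"] = share_sum / stored,
    _["n_draws"] = stored);
}
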