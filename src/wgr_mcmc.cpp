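// Single-site Gibbs sampler for whole-genome regression.
//
// BayesB: a fraction pi of SNPs has zero effect; each included effect is
// normal with its own variance carrying a scaled-inverse-chi-square prior
// (nu_j, S2_j), i.e. marginally scaled-t. The inclusion indicator is sampled
// with the effect integrated out conditional on the current SNP variance;
// excluded SNP variances are refreshed from the prior, which keeps the
// construction a valid Gibbs scheme without Metropolis tuning.
//
// BayesC0: all SNPs stay in the model and share one common variance updated
// from the pooled scaled-inverse-chi-square full conditional.
//
// Fixed hatch-within-generation class effects have flat priors; the
// residual variance has a scaled-inverse-chi-square prior (nu_e, S2_e).
// Uses R's RNG throughout so set.seed() governs reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double rinvchisq(double df, double scale) {
  // scaled inverse chi-square draw: df * scale / chisq(df)
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".wgr_mcmc_cpp")]]
List wgr_mcmc_cpp(const arma::mat& Z,
                  const arma::vec& y,
                  const arma::ivec& class_idx, // 0-based, one per record
                  int n_classes,
                  double pi_zero,
                  double nu_j, double S2_j,
                  double nu_e, double S2_e,
                  int niter, int burnin,
                  bool common_variance,
                  bool fix_var_u, double sigma2_u_fix,
                  bool fix_var_e, double sigma2_e_fix) {
  const int n = Z.n_rows, p = Z.n_cols;
  if (niter <= burnin) stop("chain_length must exceed burn_in");

  // class membership lists and counts
  std::vector<std::vector<int>> members(n_classes);
  for (int i = 0; i < n; ++i) members[class_idx[i]].push_back(i);

  arma::vec zz(p);
  for (int j = 0; j < p; ++j) zz[j] = arma::dot(Z.col(j), Z.col(j));

  const double prior_var_j = (nu_j > 2.0) ? S2_j * nu_j / (nu_j - 2.0) : S2_j;
  arma::vec u(p, arma::fill::zeros);
  arma::vec sigma2_j(p);
  sigma2_j.fill(fix_var_u ? sigma2_u_fix : prior_var_j);
  double sigma2_u = fix_var_u ? sigma2_u_fix : prior_var_j; // BayesC0 common
  double sigma2_e = fix_var_e ? sigma2_e_fix
                              : ((nu_e > 2.0) ? S2_e * nu_e / (nu_e - 2.0)
                                              : S2_e);

  arma::vec beta(n_classes, arma::fill::zeros);
  for (int m = 0; m < n_classes; ++m) {
    double s = 0.0;
    for (int i : members[m]) s += y[i];
    beta[m] = members[m].empty() ? 0.0 : s / members[m].size();
  }
  arma::vec e = y;
  for (int i = 0; i < n; ++i) e[i] -= beta[class_idx[i]];
  arma::vec g(n, arma::fill::zeros); // model-implied genetic values

  const double log_prior_odds =
      std::log((1.0 - pi_zero)) - std::log(std::max(pi_zero, 1e-300));

  arma::vec u_sum(p, arma::fill::zeros);
  arma::vec d_sum(p, arma::fill::zeros);
  arma::vec beta_sum(n_classes, arma::fill::zeros);
  arma::vec varg_chain(niter), vare_chain(niter), h2_chain(niter),
      s2u_chain(niter);
  int n_keep = 0;

  RNGScope scope;
  for (int iter = 0; iter < niter; ++iter) {
    // fixed class effects (flat prior)
    for (int m = 0; m < n_classes; ++m) {
      const std::vector<int>& mem = members[m];
      if (mem.empty()) continue;
      double s = 0.0;
      for (int i : mem) s += e[i] + beta[m];
      double mean = s / mem.size();
      double bnew = mean + norm_rand() * std::sqrt(sigma2_e / mem.size());
      double diff = bnew - beta[m];
      for (int i : mem) e[i] -= diff;
      beta[m] = bnew;
    }

    // SNP effects
    for (int j = 0; j < p; ++j) {
      if (zz[j] <= 0.0) { u[j] = 0.0; continue; }
      const double s2j = common_variance ? sigma2_u : sigma2_j[j];
      const double u_old = u[j];
      double r = arma::dot(Z.col(j), e) + zz[j] * u_old;
      bool include = true;
      if (!common_variance && pi_zero > 0.0) {
        // indicator with the effect integrated out given sigma2_j:
        // r ~ N(0, zz*s2e) under delta=0, N(0, zz*s2e + zz^2*s2j) under 1
        const double v0 = zz[j] * sigma2_e;
        const double v1 = v0 + zz[j] * zz[j] * s2j;
        const double logodds = log_prior_odds
          - 0.5 * (std::log(v1) - std::log(v0))
          - 0.5 * r * r * (1.0 / v1 - 1.0 / v0);
        const double p1 = 1.0 / (1.0 + std::exp(-logodds));
        include = unif_rand() < p1;
      }
      double u_new = 0.0;
      if (include) {
        const double c = zz[j] + sigma2_e / s2j;
        u_new = r / c + norm_rand() * std::sqrt(sigma2_e / c);
      }
      if (u_new != u_old) {
        const double diff = u_new - u_old;
        e -= diff * Z.col(j);
        g += diff * Z.col(j);
        u[j] = u_new;
      }
      if (!common_variance && !fix_var_u) {
        sigma2_j[j] = include
          ? rinvchisq(nu_j + 1.0,
                      (nu_j * S2_j + u_new * u_new) / (nu_j + 1.0))
          : rinvchisq(nu_j, S2_j);
      }
      if (iter >= burnin) {
        if (include) d_sum[j] += 1.0;
      }
    }

    if (common_variance && !fix_var_u) {
      const double ssu = arma::dot(u, u);
      sigma2_u = rinvchisq(nu_j + p, (nu_j * S2_j + ssu) / (nu_j + p));
    }
    if (!fix_var_e) {
      const double sse = arma::dot(e, e);
      sigma2_e = rinvchisq(nu_e + n, (nu_e * S2_e + sse) / (nu_e + n));
      if (!std::isfinite(sigma2_e) || sigma2_e <= 0.0)
        stop("non-finite residual variance at iteration %d", iter + 1);
    }

    const double varg = arma::var(g); // sample variance, N-1 denominator
    varg_chain[iter] = varg;
    vare_chain[iter] = sigma2_e;
    h2_chain[iter] = varg / (varg + sigma2_e);
    s2u_chain[iter] = common_variance ? sigma2_u : arma::mean(sigma2_j);

    if (iter >= burnin) {
      u_sum += u;
      beta_sum += beta;
      ++n_keep;
    }
  }

  return List::create(
      _["u_hat"] = u_sum / n_keep,
      _["incl_prob"] = common_variance
          ? arma::vec(p, arma::fill::ones)
          : arma::vec(d_sum / n_keep),
      _["beta_hat"] = beta_sum / n_keep,
      _["varg_chain"] = varg_chain,
      _["vare_chain"] = vare_chain,
      _["h2_chain"] = h2_chain,
      _["sigma2_u_chain"] = s2u_chain,
      _["n_keep"] = n_keep);
}
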