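// Gibbs sampler for Gaussian mixed models with kernel-structured random
// effects (RKHS regression). Each random effect g_i ~ N(0, K_i s2_i) is
// reparameterized through the eigendecomposition K_i = U_i D_i U_i',
// g_i = U_i delta_i with delta_i ~ N(0, D_i s2_i); because U_i has
// orthonormal columns the full conditional of delta_i factorizes into
// independent univariate normals, which is mathematically exact, not an
// approximation. Variances get scaled-inverse-chi-square full conditionals.
// All randomness flows through R's RNG so set.seed() on the R side gives
// bit-reproducible chains.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List gibbs_rkhs_cpp(const arma::vec& y,
                    const arma::mat& X,
                    const List& U_list,
                    const List& d_list,
                    const double df0,
                    const arma::vec& S0_terms,
                    const double S0_resid,
                    const double beta_prior_var,
                    const int n_iter,
                    const int burn_in,
                    const int thin) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int k = U_list.size();

  std::vector<arma::mat> U(k);
  std::vector<arma::vec> d(k);
  for (int i = 0; i < k; ++i) {
    U[i] = as<arma::mat>(U_list[i]);
    d[i] = as<arma::vec>(d_list[i]);
  }

  const arma::mat XtX = X.t() * X;
  const double vy = arma::var(y);

  // state
  arma::vec beta(p, arma::fill::zeros);
  std::vector<arma::vec> delta(k), g(k);
  for (int i = 0; i < k; ++i) {
    delta[i].zeros(d[i].n_elem);
    g[i].zeros(n);
  }
  arma::vec s2(k);
  s2.fill(vy > 0 ? vy / (2.0 * std::max(k, 1)) : 1.0);
  double s2e = vy > 0 ? vy / 2.0 : 1.0;

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat s2_draws(n_keep, k + 1);
  arma::mat beta_draws(n_keep, p);
  std::vector<arma::vec> g_sum(k);
  for (int i = 0; i < k; ++i) g_sum[i].zeros(n);
  int kept = 0;

  arma::vec resid = y - X * beta;  // y - Xb - sum g (all g zero at start)

  for (int it = 1; it <= n_iter; ++it) {
    // --- fixed effects ---
    resid += X * beta;  // residual without beta contribution
    arma::mat C = XtX / s2e;
    C.diag() += 1.0 / beta_prior_var;
    arma::mat L = arma::chol(C, "lower");
    arma::vec rhs = X.t() * resid / s2e;
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), rhs));
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z[j] = R::norm_rand();
    beta = mu + arma::solve(arma::trimatu(L.t()), z);
    resid -= X * beta;

    // --- random effects, one kernel at a time ---
    for (int i = 0; i < k; ++i) {
      resid += g[i];
      arma::vec v = U[i].t() * resid;
      const int ri = d[i].n_elem;
      for (int j = 0; j < ri; ++j) {
        const double cvar = 1.0 / (1.0 / s2e + 1.0 / (d[i][j] * s2[i]));
        const double cmean = cvar * v[j] / s2e;
        delta[i][j] = cmean + std::sqrt(cvar) * R::norm_rand();
      }
      g[i] = U[i] * delta[i];
      resid -= g[i];

      // variance update for this term
      double q = 0.0;
      for (int j = 0; j < ri; ++j) q += delta[i][j] * delta[i][j] / d[i][j];
      s2[i] = (df0 * S0_terms[i] + q) / R::rchisq(df0 + ri);
    }

    // --- residual variance ---
    const double sse = arma::dot(resid, resid);
    s2e = (df0 * S0_resid + sse) / R::rchisq(df0 + n);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int i = 0; i < k; ++i) {
        s2_draws(kept, i) = s2[i];
        g_sum[i] += g[i];
      }
      s2_draws(kept, k) = s2e;
      beta_draws.row(kept) = beta.t();
      ++kept;
    }
  }

  List g_mean(k);
  for (int i = 0; i < k; ++i)
    g_mean[i] = NumericVector(wrap(g_sum[i] / std::max(kept, 1)));

  return List::create(_["sigma2"] = s2_draws,
                      _["beta"] = beta_draws,
                      _["g_mean"] = g_mean,
                      _["n_kept"] = kept);
}
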