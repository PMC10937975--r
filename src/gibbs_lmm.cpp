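// Blocked Gibbs sampler for the pairwise linear mixed model
//   y_p = x_p' beta + sum_s z_{ps} lambda_s + eps_p
// with conjugate priors:
//   beta_k  ~ N(0, 1/beta_prec)
//   lambda_s ~ N(0, 1/tau_lambda),  tau_lambda ~ Gamma(a_l, b_l)
//   eps_p   ~ N(0, 1/tau_eps),      tau_eps   ~ Gamma(a_e, b_e)
// Full conditionals are exact (Normal-Normal-Gamma conjugacy):
// a joint multivariate-normal update for beta, scalar normal updates
// for each lambda_s, gamma updates for the two precisions.
// All randomness goes through R's RNG so set.seed() controls the draw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// one N(0,1) vector via R's RNG
static arma::vec rnorm_vec(int n) {
  NumericVector z = Rcpp::rnorm(n);
  return arma::vec(z.begin(), n, /*copy_aux_mem*/ true);
}

// [[Rcpp::export]]
arma::mat gibbs_lmm_cpp(const arma::vec& y,
                        const arma::mat& X,
                        const arma::mat& Z,
                        const double beta_prec,
                        const double a_e, const double b_e,
                        const double a_l, const double b_l,
                        const int n_iter, const int burnin, const int thin,
                        const arma::vec& beta_init,
                        const double fixed_resid_prec, // <= 0: estimate
                        const bool include_random) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int S = include_random ? Z.n_cols : 0;

  arma::vec beta = beta_init;
  arma::vec lambda = arma::zeros(S > 0 ? S : 1);
  double tau_e = fixed_resid_prec > 0 ? fixed_resid_prec : 1.0;
  double tau_l = 1.0;

  const arma::mat XtX = X.t() * X;
  // per-species sum of squared incidence coefficients
  arma::vec zss(S > 0 ? S : 1, arma::fill::zeros);
  if (S > 0)
    for (int s = 0; s < S; ++s) zss(s) = arma::dot(Z.col(s), Z.col(s));

  const int n_keep = (n_iter - burnin) / thin;
  // columns: beta (p), lambda (S), sigma2_resid, sigma2_lambda
  arma::mat out(n_keep, p + S + 2);

  RNGScope scope;
  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    arma::vec zl = (S > 0) ? arma::vec(Z * lambda.head(S)) : arma::zeros(n);

    // --- beta | rest : MVN ---
    arma::mat prec = tau_e * XtX;
    prec.diag() += beta_prec;
    arma::mat V = arma::inv_sympd(prec);
    arma::vec m = V * (tau_e * (X.t() * (y - zl)));
    arma::mat L = arma::chol(V, "lower");
    beta = m + L * rnorm_vec(p);

    arma::vec xb = X * beta;

    // --- lambda_s | rest : scalar normal ---
    if (S > 0) {
      arma::vec resid = y - xb - Z * lambda.head(S);
      for (int s = 0; s < S; ++s) {
        // residual with species s's contribution added back
        arma::vec rs = resid + Z.col(s) * lambda(s);
        double prec_s = tau_e * zss(s) + tau_l;
        double mean_s = tau_e * arma::dot(Z.col(s), rs) / prec_s;
        double newval = mean_s + R::rnorm(0.0, 1.0) / std::sqrt(prec_s);
        resid = rs - Z.col(s) * newval;
        lambda(s) = newval;
      }
    }

    // --- precisions | rest : gamma ---
    arma::vec zl2 = (S > 0) ? arma::vec(Z * lambda.head(S)) : arma::zeros(n);
    arma::vec e = y - xb - zl2;
    if (fixed_resid_prec <= 0) {
      double rate_e = b_e + 0.5 * arma::dot(e, e);
      tau_e = R::rgamma(a_e + 0.5 * n, 1.0 / rate_e); // R::rgamma takes scale
    }
    if (S > 0) {
      double rate_l = b_l + 0.5 * arma::dot(lambda.head(S), lambda.head(S));
      tau_l = R::rgamma(a_l + 0.5 * S, 1.0 / rate_l);
    }

    if (it > burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      for (int k = 0; k < p; ++k) out(kept, k) = beta(k);
      for (int s = 0; s < S; ++s) out(kept, p + s) = lambda(s);
      out(kept, p + S) = 1.0 / tau_e;
      out(kept, p + S + 1) = (S > 0) ? 1.0 / tau_l : NA_REAL;
      ++kept;
    }
  }
  return out;
}
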