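// Marginal-likelihood MCMC for the hierarchical design-bias model.
//
// Model, for response i and design j = 1..J:
//   beta_hat_i ~ MVN(beta_i * 1 + gamma_i, lambda * D_i Omega D_i),
//   beta_i ~ N(0, sigma_beta^2), gamma_ij ~ N(0, sigma_j^2),
//   D_i = diag(se_i).
// beta_i and gamma_i are integrated out analytically, so the sampler works
// on the (2 + J + J(J-1)/2)-dimensional hyperparameter space only:
//   beta_hat_i ~ MVN(0, sigma_beta^2 11' + diag(sigma^2) + lambda D_i Omega D_i).
//
// Unconstrained parameterisation:
//   u[0]        = log sigma_beta
//   u[1..J]     = log sigma_j
//   u[J+1]      = log lambda
//   u[J+2..]    = atanh of C-vine canonical partial correlations of Omega,
//                 pair order (1,2),(1,3),...,(1,J),(2,3),...,(J-1,J)
// Under LKJ(eta) the vine partials are independent 2*Beta(a,a)-1 with
// a = eta + (J - 1 - level)/2, giving the tractable log-density used below
// (the +1 in the exponent absorbs the tanh Jacobian).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat vine_to_corr(const vec& r, const int J) {
  mat P(J, J, fill::zeros);
  int idx = 0;
  for (int i = 0; i < J - 1; ++i)
    for (int j = i + 1; j < J; ++j)
      P(i, j) = r(idx++);
  mat R(J, J, fill::eye);
  for (int i = 0; i < J - 1; ++i) {
    for (int j = i + 1; j < J; ++j) {
      double rho = P(i, j);
      for (int k = i - 1; k >= 0; --k)
        rho = rho * std::sqrt((1.0 - P(k, i) * P(k, i)) *
                              (1.0 - P(k, j) * P(k, j))) + P(k, i) * P(k, j);
      R(i, j) = R(j, i) = rho;
    }
  }
  return R;
}

// [[Rcpp::export]]
arma::mat vine_corr_cpp(const arma::vec& partials, const int J) {
  return vine_to_corr(partials, J);
}

// fixed-size (J <= 8) per-response Gaussian likelihood; in-place Cholesky on
// stack arrays keeps the MCMC inner loop allocation-free
static const int JMAX = 8;

static double mvn_loglik(const mat& bh, const mat& se, const double sigma_beta,
                         const vec& sigma, const double lambda,
                         const mat& Omega) {
  const int J = bh.n_cols;
  const int n = bh.n_rows;
  if (J > JMAX) Rcpp::stop("at most 8 designs supported");
  double A[JMAX][JMAX], Om[JMAX][JMAX], S[JMAX][JMAX];
  double s_i[JMAX], y[JMAX];
  const double sb2 = sigma_beta * sigma_beta;
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < J; ++k) {
      A[j][k] = sb2 + (j == k ? sigma(j) * sigma(j) : 0.0);
      Om[j][k] = Omega(j, k);
    }
  const double cst = -0.5 * J * std::log(2.0 * M_PI);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < J; ++j) s_i[j] = se(i, j);
    for (int j = 0; j < J; ++j)
      for (int k = 0; k <= j; ++k)
        S[j][k] = A[j][k] + lambda * s_i[j] * s_i[k] * Om[j][k];
    // lower Cholesky in place
    double logdet = 0.0;
    for (int j = 0; j < J; ++j) {
      for (int k = 0; k <= j; ++k) {
        double sum = S[j][k];
        for (int m = 0; m < k; ++m) sum -= S[j][m] * S[k][m];
        if (j == k) {
          if (sum <= 0.0) return -datum::inf;
          S[j][j] = std::sqrt(sum);
          logdet += std::log(S[j][j]);
        } else {
          S[j][k] = sum / S[k][k];
        }
      }
    }
    double q = 0.0;
    for (int j = 0; j < J; ++j) {
      double sum = bh(i, j);
      for (int m = 0; m < j; ++m) sum -= S[j][m] * y[m];
      y[j] = sum / S[j][j];
      q += y[j] * y[j];
    }
    ll += cst - logdet - 0.5 * q;
  }
  return ll;
}

// [[Rcpp::export]]
double bias_loglik_cpp(const arma::mat& beta_hat, const arma::mat& se,
                       const double sigma_beta, const arma::vec& sigma,
                       const double lambda, const arma::mat& Omega) {
  return mvn_loglik(beta_hat, se, sigma_beta, sigma, lambda, Omega);
}

static double log_posterior(const vec& u, const mat& bh, const mat& se,
                            const double a_sd, const double b_sd,
                            const bool prior_on_var, const double l_shape,
                            const double l_rate, const double eta,
                            const int J) {
  double lp = 0.0;
  vec sds(J + 1);
  for (int k = 0; k <= J; ++k) {
    const double s = std::exp(u(k));
    if (!std::isfinite(s) || s <= 0.0) return -datum::inf;
    sds(k) = s;
    if (prior_on_var) {  // Inv-Gamma on the variance s^2
      lp += -(a_sd + 1.0) * 2.0 * u(k) - b_sd / (s * s) + std::log(2.0) + 2.0 * u(k);
    } else {             // Inv-Gamma on the standard deviation s
      lp += -(a_sd + 1.0) * u(k) - b_sd / s + u(k);
    }
  }
  const double lambda = std::exp(u(J + 1));
  if (!std::isfinite(lambda)) return -datum::inf;
  lp += l_shape * u(J + 1) - l_rate * lambda;  // Gamma prior + log Jacobian
  const int m = J * (J - 1) / 2;
  vec r(m);
  int idx = 0;
  for (int i = 0; i < J - 1; ++i) {
    for (int j = i + 1; j < J; ++j) {
      const double t = std::tanh(u(J + 2 + idx));
      r(idx) = t;
      const double alpha = eta + (J - 1.0 - (i + 1.0)) / 2.0;
      lp += alpha * std::log1p(-t * t);
      ++idx;
    }
  }
  mat Omega = vine_to_corr(r, J);
  const double ll = mvn_loglik(bh, se, sds(0), sds.subvec(1, J), lambda, Omega);
  return lp + ll;
}

// [[Rcpp::export]]
double bias_logpost_cpp(const arma::vec& u, const arma::mat& beta_hat,
                        const arma::mat& se, const double a_sd,
                        const double b_sd, const bool prior_on_var,
                        const double l_shape, const double l_rate,
                        const double eta, const int J) {
  return log_posterior(u, beta_hat, se, a_sd, b_sd, prior_on_var,
                       l_shape, l_rate, eta, J);
}

// Covariance-adaptive slice sampler. Each sweep performs one stepping-out +
// shrinkage slice update (Neal 2003) along every eigen-axis of the running
// empirical covariance of the chain; axes and widths are re-estimated during
// warmup and frozen afterwards. Rejection-free and insensitive to tuning,
// which matters for the curved sigma_j/lambda trade-off ridge of this
// posterior. Uses R's RNG so set.seed() on the R side is reproducible.
// [[Rcpp::export]]
Rcpp::List bias_mcmc_cpp(const arma::mat& beta_hat, const arma::mat& se,
                         const arma::vec& init_u, const int warmup,
                         const int draws, const int thin, const double a_sd,
                         const double b_sd, const bool prior_on_var,
                         const double l_shape, const double l_rate,
                         const double eta, const double target_accept) {
  const int J = beta_hat.n_cols;
  const int d = init_u.n_elem;
  const int m = J * (J - 1) / 2;
  vec cur = init_u;
  double cur_lp = log_posterior(cur, beta_hat, se, a_sd, b_sd, prior_on_var,
                                l_shape, l_rate, eta, J);
  if (!std::isfinite(cur_lp))
    Rcpp::stop("initial state has non-finite posterior density");

  vec mu = cur;
  mat C = 0.01 * eye(d, d);
  mat axes = eye(d, d);               // slice directions (columns)
  vec widths(d);
  widths.fill(0.5);
  mat out(draws, 2 + J + m);
  const int total = warmup + draws * thin;
  long n_evals = 0;
  const int max_step = 40, max_shrink = 100;

  for (int t = 1; t <= total; ++t) {
    // one stepping-out + shrinkage slice update per eigen-axis (Neal 2003)
    for (int k = 0; k < d; ++k) {
      const vec v = axes.col(k);
      const double w = widths(k);
      const double y = cur_lp - R::exp_rand();   // log slice level
      double a = -w * R::unif_rand();
      double b = a + w;
      int s = 0;
      while (s++ < max_step) {
        ++n_evals;
        if (log_posterior(cur + a * v, beta_hat, se, a_sd, b_sd, prior_on_var,
                          l_shape, l_rate, eta, J) <= y) break;
        a -= w;
      }
      s = 0;
      while (s++ < max_step) {
        ++n_evals;
        if (log_posterior(cur + b * v, beta_hat, se, a_sd, b_sd, prior_on_var,
                          l_shape, l_rate, eta, J) <= y) break;
        b += w;
      }
      for (s = 0; s < max_shrink; ++s) {
        const double tt = a + (b - a) * R::unif_rand();
        const double lp_t = log_posterior(cur + tt * v, beta_hat, se, a_sd,
                                          b_sd, prior_on_var, l_shape, l_rate,
                                          eta, J);
        ++n_evals;
        if (std::isfinite(lp_t) && lp_t > y) {
          cur += tt * v;
          cur_lp = lp_t;
          break;
        }
        if (tt < 0) a = tt; else b = tt;
        if (b - a < 1e-12) break;
      }
    }
    if (t <= warmup) {
      const double g = std::pow((double)t, -0.6);
      vec dev = cur - mu;
      mu += g * dev;
      C += g * (dev * dev.t() - C);
      if (t >= 50 && t % 50 == 0) {
        vec eval;
        mat evec;
        if (eig_sym(eval, evec, C + 1e-10 * eye(d, d))) {
          axes = evec;
          widths = 2.5 * sqrt(clamp(eval, 1e-10, datum::inf));
        }
      }
    } else if ((t - warmup) % thin == 0) {
      const int row = (t - warmup) / thin - 1;
      out(row, 0) = std::exp(cur(0));
      for (int j = 0; j < J; ++j) out(row, 1 + j) = std::exp(cur(1 + j));
      out(row, 1 + J) = std::exp(cur(J + 1));
      vec r(m);
      for (int k = 0; k < m; ++k) r(k) = std::tanh(cur(J + 2 + k));
      mat Om = vine_to_corr(r, J);
      int idx = 0;
      for (int i = 0; i < J - 1; ++i)
        for (int j = i + 1; j < J; ++j) out(row, 2 + J + idx++) = Om(i, j);
    }
    if (t % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("draws") = out,
    Rcpp::Named("evals_per_iter") = (double)n_evals / total,
    Rcpp::Named("final_lp") = cur_lp);
}
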