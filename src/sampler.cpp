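// Adaptive Metropolis-within-Gibbs sampler for the phylogenetic beta
// regression: coefficients theta, species effects u ~ MVN(0, C_lambda),
// dispersion gamma (log-scale random walk) and Pagel's lambda (random walk
// on [0, lambda_max]). Uses R's RNG so set.seed() governs determinism.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

// log Beta(y; mu*g, (1-mu)*g); -Inf outside support
static double beta_lpdf(double y, double mu, double g) {
  if (y <= 0.0 || y >= 1.0 || mu <= 0.0 || mu >= 1.0 || g <= 0.0)
    return R_NegInf;
  double a = mu * g, b = (1.0 - mu) * g;
  return std::lgamma(g) - std::lgamma(a) - std::lgamma(b) +
         (a - 1.0) * std::log(y) + (b - 1.0) * std::log1p(-y);
}

static double inv_logit(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// full gamma prior log-density (shape/rate), matching R's dgamma(log=TRUE)
static double gamma_lprior(double g, double shape, double rate) {
  if (g <= 0.0) return R_NegInf;
  return shape * std::log(rate) - std::lgamma(shape) +
         (shape - 1.0) * std::log(g) - rate * g;
}

// Pagel's-lambda covariance state: Cholesky, precision, log-determinant
struct LambdaState {
  arma::mat P;      // precision of C_lambda
  double logdet;    // log det C_lambda
  bool ok;
};

static LambdaState make_lambda_state(const arma::mat& C, double lam) {
  LambdaState st;
  arma::mat CL = C * lam;
  CL.diag() = C.diag();
  arma::mat R;
  st.ok = arma::chol(R, CL);
  if (!st.ok) return st;
  arma::mat Rinv;
  if (!arma::inv(Rinv, arma::trimatu(R))) { st.ok = false; return st; }
  st.P = Rinv * Rinv.t();
  st.logdet = 2.0 * arma::accu(arma::log(R.diag()));
  return st;
}

// [[Rcpp::export]]
double cpp_model_logpost(const arma::vec& y, const arma::mat& X,
                         const arma::mat& C, const arma::vec& theta,
                         const arma::vec& u, double gamma_, double lambda,
                         double prior_sd, double g_shape, double g_rate,
                         double lambda_max, bool include_lik = true) {
  const int n = y.n_elem;
  if (lambda < 0.0 || lambda > lambda_max || gamma_ <= 0.0)
    return R_NegInf;
  LambdaState st = make_lambda_state(C, lambda);
  if (!st.ok) return R_NegInf;
  double quad = arma::as_scalar(u.t() * st.P * u);
  double lp = -0.5 * (n * LOG2PI + st.logdet + quad);
  for (arma::uword j = 0; j < theta.n_elem; ++j)
    lp += -0.5 * LOG2PI - std::log(prior_sd) -
          0.5 * theta[j] * theta[j] / (prior_sd * prior_sd);
  lp += gamma_lprior(gamma_, g_shape, g_rate);
  lp += -std::log(lambda_max);
  if (include_lik) {
    arma::vec eta = X * theta + u;
    for (int i = 0; i < n; ++i) {
      double ll = beta_lpdf(y[i], inv_logit(eta[i]), gamma_);
      if (!std::isfinite(ll)) return R_NegInf;
      lp += ll;
    }
  }
  return lp;
}

// [[Rcpp::export]]
List cpp_mwg_chain(const arma::vec& y, const arma::mat& X,
                   const arma::mat& C, double prior_sd, double g_shape,
                   double g_rate, double lambda_max, int n_adapt, int n_keep,
                   bool include_lik, const arma::vec& init_theta,
                   const arma::vec& init_u, double init_gamma,
                   double init_lambda, arma::vec scale_theta,
                   arma::vec scale_u, double scale_gamma, double scale_lambda,
                   int adapt_batch = 50) {
  const int n = y.n_elem, p = X.n_cols;
  const double target = 0.44;  // scalar random-walk acceptance target

  arma::vec theta = init_theta, u = init_u;
  double gamma_ = init_gamma, lambda = init_lambda;

  LambdaState st = make_lambda_state(C, lambda);
  if (!st.ok) stop("initial lambda gives a non-positive-definite covariance");
  double quad = arma::as_scalar(u.t() * st.P * u);

  arma::vec eta = X * theta + u;
  arma::vec ll(n);
  double ll_sum = 0.0;
  for (int i = 0; i < n; ++i) {
    ll[i] = include_lik ? beta_lpdf(y[i], inv_logit(eta[i]), gamma_) : 0.0;
    ll_sum += ll[i];
  }
  if (!std::isfinite(ll_sum))
    stop("log posterior not finite at the initial state");

  arma::mat draws(n_keep, p + n + 2);
  arma::vec acc_theta(p, arma::fill::zeros), acc_u(n, arma::fill::zeros);
  double acc_gamma = 0.0, acc_lambda = 0.0, acc_shift = 0.0;
  arma::vec tot_theta(p, arma::fill::zeros), tot_u(n, arma::fill::zeros);
  double tot_gamma = 0.0, tot_lambda = 0.0, tot_shift = 0.0;
  double scale_shift = 0.5;
  // the translation move is only valid when column 0 is an intercept
  bool has_intercept = arma::all(X.col(0) == 1.0);

  const double inv2v = 0.5 / (prior_sd * prior_sd);
  int batch_count = 0;

  for (int iter = 0; iter < n_adapt + n_keep; ++iter) {
    bool adapting = iter < n_adapt;

    // --- coefficients, one at a time ---
    for (int j = 0; j < p; ++j) {
      double delta = norm_rand() * scale_theta[j];
      double lr = -inv2v * ((theta[j] + delta) * (theta[j] + delta) -
                            theta[j] * theta[j]);
      double new_sum = 0.0;
      arma::vec ll_new(n);
      if (include_lik) {
        for (int i = 0; i < n; ++i) {
          ll_new[i] = beta_lpdf(y[i], inv_logit(eta[i] + X(i, j) * delta),
                                gamma_);
          new_sum += ll_new[i];
        }
        lr += new_sum - ll_sum;
      }
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        theta[j] += delta;
        if (include_lik) {
          eta += X.col(j) * delta;
          ll = ll_new;
          ll_sum = new_sum;
        }
        acc_theta[j] += 1.0;
      }
      tot_theta[j] += 1.0;
    }

    // --- species effects, one at a time ---
    for (int i = 0; i < n; ++i) {
      double delta = norm_rand() * scale_u[i];
      double pu = arma::dot(st.P.row(i), u);
      double quad_new = quad + 2.0 * delta * pu +
                        st.P(i, i) * delta * delta;
      double lr = -0.5 * (quad_new - quad);
      double ll_i_new = 0.0;
      if (include_lik) {
        ll_i_new = beta_lpdf(y[i], inv_logit(eta[i] + delta), gamma_);
        lr += ll_i_new - ll[i];
      }
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        u[i] += delta;
        quad = quad_new;
        if (include_lik) {
          eta[i] += delta;
          ll_sum += ll_i_new - ll[i];
          ll[i] = ll_i_new;
        }
        acc_u[i] += 1.0;
      }
      tot_u[i] += 1.0;
    }

    // --- translation move along the intercept/species-effect ridge:
    //     (theta_0 + d, u - d) leaves the linear predictor unchanged, so
    //     only the priors enter the ratio; this decorrelates the intercept
    //     from the mean of u ---
    if (include_lik && has_intercept) {
      double d = norm_rand() * scale_shift;
      arma::vec P1 = st.P * arma::ones<arma::vec>(n);
      double quad_new = quad - 2.0 * d * arma::dot(u, P1) +
                        d * d * arma::accu(P1);
      double t0 = theta[0];
      double lr = -0.5 * (quad_new - quad) -
                  inv2v * ((t0 + d) * (t0 + d) - t0 * t0);
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        theta[0] += d;
        u -= d;  // eta = X theta + u is unchanged
        quad = quad_new;
        acc_shift += 1.0;
      }
      tot_shift += 1.0;
    }

    // --- dispersion, random walk on log(gamma) ---
    {
      double delta = norm_rand() * scale_gamma;
      double g_new = gamma_ * std::exp(delta);
      double lr = gamma_lprior(g_new, g_shape, g_rate) -
                  gamma_lprior(gamma_, g_shape, g_rate) + delta;  // Jacobian
      double new_sum = 0.0;
      arma::vec ll_new(n);
      if (include_lik) {
        for (int i = 0; i < n; ++i) {
          ll_new[i] = beta_lpdf(y[i], inv_logit(eta[i]), g_new);
          new_sum += ll_new[i];
        }
        lr += new_sum - ll_sum;
      }
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        gamma_ = g_new;
        if (include_lik) { ll = ll_new; ll_sum = new_sum; }
        acc_gamma += 1.0;
      }
      tot_gamma += 1.0;
    }

    // --- lambda, random walk with rejection outside the prior support and
    //     at proposals whose C_lambda is not positive definite ---
    {
      double lam_new = lambda + norm_rand() * scale_lambda;
      if (lam_new >= 0.0 && lam_new <= lambda_max) {
        LambdaState st_new = make_lambda_state(C, lam_new);
        if (st_new.ok) {
          double quad_new = arma::as_scalar(u.t() * st_new.P * u);
          double lr = -0.5 * (st_new.logdet + quad_new) +
                      0.5 * (st.logdet + quad);
          if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
            lambda = lam_new;
            st = st_new;
            quad = quad_new;
            acc_lambda += 1.0;
          }
        }
      }
      tot_lambda += 1.0;
    }

    // --- proposal-scale adaptation, during warmup only ---
    if (adapting && ((iter + 1) % adapt_batch == 0)) {
      ++batch_count;
      for (int j = 0; j < p; ++j) {
        scale_theta[j] *= std::exp(acc_theta[j] / tot_theta[j] - target);
        acc_theta[j] = tot_theta[j] = 0.0;
      }
      for (int i = 0; i < n; ++i) {
        scale_u[i] *= std::exp(acc_u[i] / tot_u[i] - target);
        acc_u[i] = tot_u[i] = 0.0;
      }
      scale_gamma *= std::exp(acc_gamma / tot_gamma - target);
      scale_lambda *= std::exp(acc_lambda / tot_lambda - target);
      if (tot_shift > 0)
        scale_shift *= std::exp(acc_shift / tot_shift - target);
      acc_gamma = tot_gamma = 0.0;
      acc_lambda = tot_lambda = 0.0;
      acc_shift = tot_shift = 0.0;
    }

    if (!adapting) {
      int r = iter - n_adapt;
      for (int j = 0; j < p; ++j) draws(r, j) = theta[j];
      for (int i = 0; i < n; ++i) draws(r, p + i) = u[i];
      draws(r, p + n) = gamma_;
      draws(r, p + n + 1) = lambda;
    }
  }

  return List::create(
    _["draws"] = draws,
    _["accept"] = List::create(
      _["theta"] = acc_theta / arma::clamp(tot_theta, 1.0, arma::datum::inf),
      _["gamma"] = tot_gamma > 0 ? acc_gamma / tot_gamma : 0.0,
      _["lambda"] = tot_lambda > 0 ? acc_lambda / tot_lambda : 0.0),
    _["scales"] = List::create(
      _["theta"] = scale_theta, _["u"] = scale_u,
      _["gamma"] = scale_gamma, _["lambda"] = scale_lambda));
}
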