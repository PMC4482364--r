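# Model specification, design matrices and the joint log posterior of the
# phylogenetic beta regression.

#' Specify the phylogenetic beta regression model
#'
#' The response y_i is Beta(mu_i * gamma, (1 - mu_i) * gamma): the
#' mean-dispersion parameterisation, where mu_i is the mean and gamma the
#' concentration. logit(mu_i) = X_i theta + u_i, with species effects
#' u ~ MVN(0, C_lambda), C_lambda the Pagel's-lambda-scaled phylogenetic
#' covariance. Priors: theta_j ~ Normal(0, sd \code{prior_coef_sd});
#' lambda ~ Uniform(0, 1.2); gamma ~ Gamma(0.001, rate 0.001) by default.
#' The dispersion prior can also be read with 0.001 as a scale parameter
#' via \code{gamma_prior_parameterization = "scale"}.
#'
#' @param form \code{"main_effects"} (region + five traits, 7 columns) or
#'   \code{"interactions"} (adds the five region-by-trait products,
#'   12 columns).
#' @param prior_coef_sd prior standard deviation of the coefficients.
#' @param lambda_max upper end of the uniform prior on lambda.
#' @param gamma_shape,gamma_value shape and second parameter of the gamma
#'   prior on the dispersion.
#' @param gamma_prior_parameterization whether \code{gamma_value} is a rate
#'   (default) or a scale.
#' @param squeeze response-compression rule id, stored for provenance.
#' @return an object of class \code{"model_spec"}.
#' @export
model_spec <- function(form = c("main_effects", "interactions"),
                       prior_coef_sd = 1000, lambda_max = 1.2,
                       gamma_shape = 0.001, gamma_value = 0.001,
                       gamma_prior_parameterization = c("rate", "scale"),
                       squeeze = "smithson") {
  form <- match.arg(form)
  par <- match.arg(gamma_prior_parameterization)
  stopifnot(prior_coef_sd > 0, gamma_shape > 0, gamma_value > 0,
            lambda_max > 0)
  structure(list(form = form, prior_coef_sd = prior_coef_sd,
                 lambda_max = lambda_max, gamma_shape = gamma_shape,
                 gamma_rate = if (par == "rate") gamma_value
                              else 1 / gamma_value,
                 gamma_prior_parameterization = par, squeeze = squeeze),
            class = "model_spec")
}

.main_effect_columns <- c("Intercept", "NS", "log Range", "log Female mass",
                          "log Rainfall", "Habitat openness", "log Litter")

#' Build the design matrix
#'
#' Main-effects form: intercept, NS, log Range, log Female mass,
#' log Rainfall, Habitat openness, log Litter (7 columns). Interactions
#' form adds the five products of NS with each non-intercept trait column
#' (12 columns). An all-zero column (e.g. interactions on a single-region
#' table) is an error.
#'
#' @param data a \code{"prepared_data"} object.
#' @param spec a \code{"model_spec"} (or a form string).
#' @return numeric matrix, rows named by taxon, columns by predictor.
#' @export
build_design <- function(data, spec = model_spec()) {
  stopifnot(inherits(data, "prepared_data"))
  if (is.character(spec)) spec <- model_spec(form = spec)
  P <- data$predictors
  X <- cbind(Intercept = 1, as.matrix(P))
  colnames(X) <- .main_effect_columns
  if (spec$form == "interactions") {
    traits <- setdiff(.main_effect_columns, c("Intercept", "NS"))
    inter <- sapply(traits, function(cn) X[, "NS"] * X[, cn])
    colnames(inter) <- paste0("NS:", traits)
    X <- cbind(X, inter)
  }
  rownames(X) <- data$taxa
  zero <- colnames(X)[colSums(abs(X)) == 0]
  if (length(zero))
    stop("design has all-zero column(s): ", paste(zero, collapse = ", "))
  X
}

#' Beta log-density in the mean-dispersion parameterisation
#'
#' log Beta(y; mu * gamma, (1 - mu) * gamma), evaluated through log-gamma
#' functions. Values of y outside the open unit interval (and invalid mu or
#' gamma) yield \code{-Inf} rather than an error, so a sampler can reject
#' such proposals.
#'
#' @param y observations; density support is (0, 1).
#' @param mu mean(s) in (0, 1).
#' @param gamma dispersion/concentration > 0.
#' @return vector of log-densities.
#' @export
beta_logpdf <- function(y, mu, gamma) {
  k <- max(length(y), length(mu), length(gamma))
  y <- rep_len(y, k); mu <- rep_len(mu, k); gamma <- rep_len(gamma, k)
  out <- rep(-Inf, k)
  ok <- y > 0 & y < 1 & mu > 0 & mu < 1 & gamma > 0
  if (any(ok)) {
    a <- mu[ok] * gamma[ok]
    b <- (1 - mu[ok]) * gamma[ok]
    out[ok] <- lgamma(a + b) - lgamma(a) - lgamma(b) +
      (a - 1) * log(y[ok]) + (b - 1) * log1p(-y[ok])
  }
  out
}

# multivariate normal log-density at mean zero via Cholesky; -Inf when the
# covariance is not (numerically) positive definite
.mvn0_logpdf <- function(u, Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  z <- backsolve(R, u, transpose = TRUE)
  -0.5 * (length(u) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

#' Joint log-prior of the model parameters
#'
#' Sum of independent Normal(0, \code{prior_coef_sd}) terms over the
#' coefficients, the Uniform(0, \code{lambda_max}) density for lambda, the
#' gamma prior for the dispersion, and a multivariate normal density with
#' zero mean and covariance \code{C_lambda} (recomputed at the current
#' lambda from the base matrix in \code{cov}) for the species effects.
#' Out-of-support values (lambda outside its prior, gamma <= 0, a
#' non-positive-definite \code{C_lambda}) give \code{-Inf}.
#'
#' @param params list with elements \code{theta}, \code{u}, \code{gamma},
#'   \code{lambda}.
#' @param spec a \code{"model_spec"}.
#' @param cov a \code{"phylo_cov"} whose taxa match \code{u}.
#' @return scalar log-density.
#' @export
log_prior <- function(params, spec, cov) {
  stopifnot(inherits(cov, "phylo_cov"))
  if (length(params$u) != length(cov$taxa))
    stop("length(u) does not match covariance dimension")
  if (params$lambda < 0 || params$lambda > spec$lambda_max) return(-Inf)
  if (params$gamma <= 0) return(-Inf)
  CL <- cov$C * params$lambda
  diag(CL) <- diag(cov$C)
  lp_u <- .mvn0_logpdf(params$u, CL)
  if (!is.finite(lp_u)) return(-Inf)
  sum(dnorm(params$theta, 0, spec$prior_coef_sd, log = TRUE)) +
    dgamma(params$gamma, shape = spec$gamma_shape, rate = spec$gamma_rate,
           log = TRUE) -
    log(spec$lambda_max) +
    lp_u
}

#' Joint log-posterior of the phylogenetic beta regression
#'
#' \code{log_prior(params, ...) + sum_i log Beta(y_i; mu_i gamma,
#' (1 - mu_i) gamma)} with \code{mu = plogis(X theta + u)}.
#'
#' @param params list with \code{theta}, \code{u}, \code{gamma},
#'   \code{lambda}.
#' @param X design matrix from [build_design()].
#' @param y compressed response strictly inside (0, 1).
#' @param cov a \code{"phylo_cov"} aligned with the rows of \code{X}.
#' @param spec a \code{"model_spec"}.
#' @return scalar log-density (possibly \code{-Inf}).
#' @export
log_posterior <- function(params, X, y, cov, spec) {
  if (length(params$theta) != ncol(X))
    stop("length(theta) does not match ncol(X)")
  if (length(params$u) != nrow(X) || length(y) != nrow(X))
    stop("u, y and X dimensions disagree")
  lp <- log_prior(params, spec, cov)
  if (!is.finite(lp)) return(-Inf)
  mu <- plogis(drop(X %*% params$theta) + params$u)
  lp + sum(beta_logpdf(y, mu, params$gamma))
}
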