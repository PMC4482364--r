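test_that("design matrices have the documented columns and nest correctly", {
  dat <- random_dataset(n_species = 10, seed = 2)
  prep <- prepare_predictors(dat$table, squeeze = "none")
  Xm <- build_design(prep, model_spec("main_effects"))
  Xi <- build_design(prep, model_spec("interactions"))
  expect_equal(ncol(Xm), 7L)
  expect_equal(ncol(Xi), 12L)
  expect_true(all(Xm[, 1] == 1))
  expect_true(all(colnames(Xm) %in% colnames(Xi)))  # main nests in interactions
  expect_equal(Xi[, colnames(Xm)], Xm)
  expect_equal(Xi[, "NS:log Range"], Xi[, "NS"] * Xi[, "log Range"],
               ignore_attr = TRUE)
  # single-region table makes interaction columns all zero -> error
  south <- dat$table[dat$table$region == "south", ]
  class(south) <- c("trait_table", "data.frame")
  prep_s <- prepare_predictors(south, squeeze = "none")
  expect_error(build_design(prep_s, model_spec("interactions")), "zero")
})

test_that("beta log-density matches closed forms and integrates to one", {
  # Beta(1, 1) is uniform
  expect_equal(beta_logpdf(0.3, 0.5, 2), 0)
  # Beta(2, 2): density 6 y (1 - y); at y = 0.5 equals 1.5
  expect_equal(beta_logpdf(0.5, 0.5, 4), log(1.5), tolerance = 1e-12)
  # closed-form log-gamma expression, independently written out
  set.seed(10)
  for (i in 1:25) {
    y <- runif(1); mu <- runif(1); g <- rexp(1, 1 / 3)
    ref <- lgamma(g) - lgamma(mu * g) - lgamma((1 - mu) * g) +
      (mu * g - 1) * log(y) + ((1 - mu) * g - 1) * log(1 - y)
    expect_equal(beta_logpdf(y, mu, g), ref, tolerance = 1e-12)
  }
  # quadrature: density integrates to 1
  q <- integrate(function(y) exp(beta_logpdf(y, 0.3, 7.2)), 0, 1,
                 rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-8)
  # out-of-support points are -Inf, not errors
  expect_identical(beta_logpdf(c(0, 1, -0.1), 0.5, 2), rep(-Inf, 3))
  expect_identical(beta_logpdf(0.5, 0.5, -1), -Inf)
})

test_that("log-prior terms match closed forms", {
  C <- diag(c(1, 2, 3))
  dimnames(C) <- list(paste0("t", 1:3), paste0("t", 1:3))
  cov <- as_phylo_cov(C)
  spec <- model_spec()
  base <- list(theta = 0, u = rep(0, 3), gamma = 1, lambda = 0.5)

  # out-of-support lambda and gamma
  expect_identical(log_prior(modifyList(base, list(lambda = 1.3)), spec, cov),
                   -Inf)
  expect_identical(log_prior(modifyList(base, list(gamma = -1)), spec, cov),
                   -Inf)

  # a single zero coefficient contributes -ln(1000) - 0.5 ln(2 pi)
  lp1 <- log_prior(base, spec, cov)
  lp2 <- log_prior(modifyList(base, list(theta = c(0, 0))), spec, cov)
  expect_equal(lp2 - lp1, -log(1000) - 0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(-log(1000) - 0.5 * log(2 * pi), -7.826694, tolerance = 1e-6)

  # u at the MVN mean contributes -0.5 log det(2 pi C_lambda)
  CL <- C * 0.5; diag(CL) <- diag(C)
  mvn_at_mean <- -0.5 * determinant(2 * pi * CL, logarithm = TRUE)$modulus
  with_u <- log_prior(base, spec, cov)
  without_u <- sum(dnorm(0, 0, 1000, log = TRUE)) +
    dgamma(1, 0.001, rate = 0.001, log = TRUE) - log(1.2)
  expect_equal(with_u - without_u, as.numeric(mvn_at_mean), tolerance = 1e-10)
})

test_that("the MVN species prior factorises on a diagonal covariance", {
  C <- diag(c(1.5, 2.5, 0.7, 1.1))
  cov <- as_phylo_cov(C)
  spec <- model_spec()
  u <- c(0.3, -1, 0.5, 2)
  pars <- list(theta = numeric(0), u = u, gamma = 1, lambda = 0)
  lp <- log_prior(pars, spec, cov)
  lp_ref <- sum(dnorm(u, 0, sqrt(diag(C)), log = TRUE)) +
    dgamma(1, 0.001, rate = 0.001, log = TRUE) - log(1.2)
  expect_equal(lp, lp_ref, tolerance = 1e-10)
})

test_that("log-posterior equals the sum of its parts and respects permutations", {
  dat <- random_dataset(n_species = 8, seed = 3)
  prep <- prepare_predictors(dat$table, squeeze = "none")
  spec <- model_spec()
  X <- build_design(prep, spec)
  n <- nrow(X)
  set.seed(4)
  pars <- list(theta = rnorm(ncol(X)), u = rnorm(n), gamma = 2, lambda = 0.7)

  # component-sum oracle
  mu <- plogis(drop(X %*% pars$theta) + pars$u)
  ref <- log_prior(pars, spec, dat$cov) +
    sum(beta_logpdf(prep$y, mu, pars$gamma))
  expect_equal(log_posterior(pars, X, prep$y, dat$cov, spec), ref,
               tolerance = 1e-10)

  # permutation invariance
  perm <- sample(n)
  cov_p <- dat$cov
  cov_p$C <- dat$cov$C[perm, perm]
  cov_p$taxa <- dat$cov$taxa[perm]
  pars_p <- pars; pars_p$u <- pars$u[perm]
  expect_equal(log_posterior(pars_p, X[perm, ], prep$y[perm], cov_p, spec),
               log_posterior(pars, X, prep$y, dat$cov, spec),
               tolerance = 1e-10)

  # changing theta, u at fixed gamma changes only the likelihood term
  pars2 <- pars; pars2$theta <- 2 * pars$theta; pars2$u <- 2 * pars$u
  mu2 <- plogis(drop(X %*% pars2$theta) + pars2$u)
  lhs <- log_posterior(pars2, X, prep$y, dat$cov, spec) -
    log_posterior(pars, X, prep$y, dat$cov, spec)
  rhs <- (log_prior(pars2, spec, dat$cov) - log_prior(pars, spec, dat$cov)) +
    sum(beta_logpdf(prep$y, mu2, pars$gamma)) -
    sum(beta_logpdf(prep$y, mu, pars$gamma))
  expect_equal(lhs, rhs, tolerance = 1e-10)

  # out-of-support dispersion
  expect_identical(
    log_posterior(modifyList(pars, list(gamma = -1)), X, prep$y, dat$cov,
                  spec), -Inf)
  expect_error(log_posterior(modifyList(pars, list(theta = 1)), X, prep$y,
                             dat$cov, spec), "theta")
})

test_that("compiled and reference log-posteriors agree", {
  dat <- random_dataset(n_species = 9, seed = 6)
  prep <- prepare_predictors(dat$table, squeeze = "none")
  spec <- model_spec()
  X <- build_design(prep, spec)
  set.seed(8)
  for (i in 1:10) {
    pars <- list(theta = rnorm(ncol(X), 0, 2), u = rnorm(nrow(X), 0, 2),
                 gamma = rexp(1, 1 / 2), lambda = runif(1, 0, 1.1))
    a <- log_posterior(pars, X, prep$y, dat$cov, spec)
    b <- phylobeta:::cpp_model_logpost(
      prep$y, X, dat$cov$C, pars$theta, pars$u, pars$gamma, pars$lambda,
      spec$prior_coef_sd, spec$gamma_shape, spec$gamma_rate, spec$lambda_max,
      TRUE)
    if (is.finite(a)) expect_equal(a, b, tolerance = 1e-9)
    else expect_identical(b, -Inf)
  }
})

test_that("the dispersion prior supports both parameterisations", {
  rate_spec <- model_spec(gamma_value = 0.001,
                          gamma_prior_parameterization = "rate")
  scale_spec <- model_spec(gamma_value = 0.001,
                           gamma_prior_parameterization = "scale")
  expect_equal(rate_spec$gamma_rate, 0.001)
  expect_equal(scale_spec$gamma_rate, 1000)
})
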