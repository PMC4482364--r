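test_that("run_chains is deterministic and rejects a bad start", {
  lp <- function(x) sum(dnorm(x, log = TRUE))
  a <- run_chains(lp, c(z = 0), n_chains = 2, n_adapt = 100, n_keep = 200,
                  seed = 5)
  b <- run_chains(lp, c(z = 0), n_chains = 2, n_adapt = 100, n_keep = 200,
                  seed = 5)
  expect_identical(a$chains, b$chains)
  c2 <- run_chains(lp, c(z = 0), n_chains = 2, n_adapt = 100, n_keep = 200,
                   seed = 6)
  expect_false(identical(a$chains, c2$chains))
  expect_error(run_chains(function(x) -Inf, c(z = 0)), "finite")
  # combined-chain inference path: concatenation has n_chains * n_keep rows
  expect_equal(nrow(combine_chains(a)), 2 * 200)
})

test_that("run_chains recovers a conjugate normal posterior", {
  # y ~ N(theta, 1), n = 5, ybar = 1.2; theta ~ N(0, 2^2)
  ybar <- 1.2; n <- 5; v0 <- 4
  post_var <- 1 / (n + 1 / v0)
  post_mean <- post_var * n * ybar
  lp <- function(x) -0.5 * n * (ybar - x)^2 - 0.5 * x^2 / v0
  ch <- run_chains(lp, c(theta = 0), n_chains = 2, n_adapt = 500,
                   n_keep = 4000, seed = 9)
  draws <- combine_chains(ch)[, "theta"]
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse(draws))
  expect_equal(sd(draws), sqrt(post_var), tolerance = 0.1)
})

test_that("split-chain R-hat matches a hand-computed example and separates bad chains", {
  # two chains of 4 draws; halves (1,2) (3,4) (2,4) (6,8)
  chains <- list(c(1, 2, 3, 4), c(2, 4, 6, 8))
  halves <- list(c(1, 2), c(3, 4), c(2, 4), c(6, 8))
  n <- 2
  W <- mean(sapply(halves, var))
  B <- n * var(sapply(halves, mean))
  expected <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(as.numeric(gelman_rubin(chains)), expected, tolerance = 1e-12)

  set.seed(31)
  same <- list(rnorm(10000), rnorm(10000))
  expect_true(gelman_rubin(same) > 0.999 && gelman_rubin(same) < 1.01)
  apart <- list(rnorm(1000), rnorm(1000, mean = 10))
  expect_gt(gelman_rubin(apart), 1.5)
  flat <- list(rep(1, 100), rep(1, 100))
  expect_true(is.na(gelman_rubin(flat)))
  expect_true(attr(gelman_rubin(flat), "degenerate"))
})

test_that("autocorrelation uses the biased estimator with rho_0 = 1", {
  set.seed(17)
  x <- rnorm(4000)
  rho <- autocorrelation(x, 40)
  expect_equal(rho[1], 1)
  # white-noise band: ~99% of lags within 3/sqrt(n)
  expect_gte(mean(abs(rho[-1]) < 3 / sqrt(length(x))), 0.95)
  # alternating series: rho_1 = -(n-1)/n under the n-denominator estimator
  alt <- rep(c(1, -1), 500)
  n <- length(alt)
  expect_equal(autocorrelation(alt, 1)[2], -(n - 1) / n, tolerance = 1e-12)
  expect_error(autocorrelation(x, 2001), "n/2")
})

test_that("effective sample size tracks the iid and AR(1) limits", {
  set.seed(23)
  x <- rnorm(10000)
  expect_equal(effective_sample_size(x), 10000, tolerance = 0.1)
  # AR(1), rho = 0.9: ESS -> n (1 - rho) / (1 + rho) = n / 19
  n <- 50000
  ar <- as.numeric(filter(rnorm(n), 0.9, method = "recursive"))
  expect_equal(effective_sample_size(ar), n / 19, tolerance = 0.15)
  cst <- rep(2, 100)
  expect_equal(as.numeric(effective_sample_size(cst)), 1)
  expect_true(attr(effective_sample_size(cst), "degenerate"))
  # ESS rises monotonically as autocorrelation decreases
  ess <- sapply(c(0.9, 0.6, 0.3), function(r) {
    set.seed(40)
    effective_sample_size(as.numeric(filter(rnorm(20000), r,
                                            method = "recursive")))
  })
  expect_true(all(diff(ess) > 0))
})

test_that("ESS broadly agrees with coda's estimator on AR(1) chains", {
  skip_if_not_installed("coda")
  set.seed(29)
  x <- as.numeric(filter(rnorm(30000), 0.8, method = "recursive"))
  ours <- effective_sample_size(x)
  theirs <- coda::effectiveSize(x)
  expect_equal(as.numeric(ours), as.numeric(theirs), tolerance = 0.25)
})

test_that("HPD intervals match the exhaustive-window search", {
  # regular grid: all windows tie, the lowest start wins
  grid <- seq(0, 0.99, by = 0.01)
  expect_equal(hpd_interval(grid, 0.95), c(0, 0.94))
  # random draw sets against the brute-force oracle
  set.seed(37)
  for (i in 1:20) {
    n <- sample(20:2000, 1)
    draws <- switch(1 + i %% 3, rnorm(n), rexp(n), rbeta(n, 0.5, 2))
    expect_equal(hpd_interval(draws, 0.95), brute_force_hpd(draws, 0.95))
    expect_equal(hpd_interval(draws, 0.5), brute_force_hpd(draws, 0.5))
  }
  # point mass
  expect_equal(hpd_interval(rep(3.3, 50)), c(3.3, 3.3))
  # large normal sample approaches the analytic 95% interval
  set.seed(41)
  z <- rnorm(100000)
  hp <- hpd_interval(z, 0.95)
  expect_equal(hp, c(-1.96, 1.96), tolerance = 0.03)
})

test_that("MCSE follows sd/sqrt(ESS)", {
  set.seed(43)
  x <- rnorm(10000)
  expect_equal(mcse(x), 0.01, tolerance = 0.1)
  ar <- as.numeric(filter(rnorm(50000), 0.9, method = "recursive"))
  expect_equal(mcse(ar), sd(ar) * sqrt(19 / length(ar)), tolerance = 0.1)
  expect_identical(as.numeric(mcse(rep(1, 100))), 0)
})

test_that("model chains are reproducible and lambda stays inside its prior", {
  dat <- random_dataset(n_species = 8, seed = 13)
  prep <- prepare_predictors(dat$table, squeeze = "none")
  spec <- model_spec()
  X <- build_design(prep, spec)
  f1 <- fit_model(prep$y, X, dat$cov, spec, n_chains = 2, n_adapt = 100,
                  n_keep = 300, seed = 3)
  f2 <- fit_model(prep$y, X, dat$cov, spec, n_chains = 2, n_adapt = 100,
                  n_keep = 300, seed = 3)
  expect_identical(f1$chains, f2$chains)
  M <- combine_chains(f1)
  expect_true(all(M[, "lambda"] >= 0 & M[, "lambda"] <= 1.2))
  expect_true(all(M[, "gamma"] > 0))
})
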