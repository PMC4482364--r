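# MCMC drivers: a generic adaptive Metropolis-within-Gibbs sampler over an
# arbitrary log-posterior callable, and the model-specific fitting front end
# backed by the compiled sampler.

# deterministic per-chain seeds below 2^31, derived from one master seed
.chain_seeds <- function(seed, n_chains) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_chains)
}

.new_chain_set <- function(chains, n_adapt, n_keep, seed,
                           param_names = colnames(chains[[1]]), extra = list()) {
  structure(c(list(chains = chains, n_chains = length(chains),
                   n_adapt = n_adapt, n_keep = n_keep, seed = seed,
                   param_names = param_names), extra),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("chain_set: %d chains x %d kept draws (%d adaptation), %d parameters, seed %d\n",
              x$n_chains, x$n_keep, x$n_adapt, length(x$param_names), x$seed))
  invisible(x)
}

#' Combine chains into a single matrix
#'
#' After convergence checks, inference is based on the concatenation of all
#' chains into one sequence of length \code{n_chains * n_keep}.
#'
#' @param chains a \code{"chain_set"}.
#' @return numeric matrix (draws x parameters).
#' @export
combine_chains <- function(chains) {
  stopifnot(inherits(chains, "chain_set"))
  do.call(rbind, chains$chains)
}

#' Run adaptive Metropolis-within-Gibbs chains over a log-posterior
#'
#' A generic scalar-update random-walk sampler: each coordinate of the state
#' is updated in turn with a Gaussian proposal whose scale is adapted toward
#' a 0.44 acceptance rate during the (discarded) adaptation phase only.
#' Per-chain RNG streams are derived deterministically from \code{seed}, so
#' the same seed reproduces the draws exactly.
#'
#' This is the general-purpose entry point (any finite log-density works);
#' the phylogenetic beta regression itself is fitted by the faster
#' specialised implementation behind [fit_model()].
#'
#' @param logpost function taking a named numeric vector, returning a scalar
#'   log-density (\code{-Inf} allowed away from the initial state).
#' @param init named numeric vector; \code{logpost(init)} must be finite.
#' @param n_chains,n_adapt,n_keep chain count, discarded adaptation length
#'   and kept length.
#' @param seed master seed.
#' @param prop_scale initial proposal standard deviation(s), recycled over
#'   coordinates.
#' @param adapt_batch iterations per adaptation step.
#' @return a \code{"chain_set"}.
#' @export
run_chains <- function(logpost, init, n_chains = 4, n_adapt = 500,
                       n_keep = 5000, seed = 1, prop_scale = 1,
                       adapt_batch = 50) {
  d <- length(init)
  if (is.null(names(init))) names(init) <- paste0("par", seq_len(d))
  lp0 <- logpost(init)
  if (!is.finite(lp0)) stop("log posterior not finite at init")
  scales0 <- rep_len(prop_scale, d)
  seeds <- .chain_seeds(seed, n_chains)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seeds[ch])
    x <- init
    lp <- lp0
    s <- scales0
    acc <- tot <- numeric(d)
    keep <- matrix(NA_real_, n_keep, d, dimnames = list(NULL, names(init)))
    for (iter in seq_len(n_adapt + n_keep)) {
      for (j in seq_len(d)) {
        prop <- x
        prop[j] <- x[j] + rnorm(1, 0, s[j])
        lp_new <- logpost(prop)
        if (is.finite(lp_new) && log(runif(1)) < lp_new - lp) {
          x <- prop
          lp <- lp_new
          acc[j] <- acc[j] + 1
        }
        tot[j] <- tot[j] + 1
      }
      if (iter <= n_adapt && iter %% adapt_batch == 0) {
        s <- s * exp(acc / tot - 0.44)
        acc <- tot <- numeric(d)
      }
      if (iter > n_adapt) keep[iter - n_adapt, ] <- x
    }
    chains[[ch]] <- keep
  }
  .new_chain_set(chains, n_adapt, n_keep, seed)
}

#' Fit the phylogenetic beta regression by MCMC
#'
#' Samples the joint posterior of the coefficients, species effects,
#' dispersion gamma and Pagel's lambda with a compiled adaptive
#' Metropolis-within-Gibbs sampler: scalar random-walk updates for each
#' coefficient and species effect, a log-scale random walk for gamma, and a
#' random walk for lambda with proposals rejected outside its prior support
#' or where the lambda-scaled covariance loses positive definiteness.
#' Proposal scales adapt only during the discarded phase.
#'
#' @param y compressed response strictly inside (0, 1).
#' @param X design matrix from [build_design()].
#' @param cov a \code{"phylo_cov"} over the same taxa (base matrix C; the
#'   lambda transform is applied internally at each sampled lambda).
#' @param spec a \code{"model_spec"}.
#' @param n_chains,n_adapt,n_keep sampler settings (defaults 4 chains of
#'   500 + 5000; the study-scale 1000 + 50000 is configurable).
#' @param seed master seed; per-chain streams are derived from it.
#' @param init optional named list (\code{theta}, \code{u}, \code{gamma},
#'   \code{lambda}) overriding the default initial state.
#' @param include_likelihood set \code{FALSE} to sample the prior only
#'   (used for prior-recovery checks).
#' @param prop_scale named list overriding initial proposal scales
#'   (\code{theta}, \code{u}, \code{gamma}, \code{lambda}).
#' @return a \code{"chain_set"} whose columns are the named coefficients,
#'   \code{u[taxon]} effects, \code{gamma} and \code{lambda}.
#' @export
fit_model <- function(y, X, cov, spec = model_spec(), n_chains = 4,
                      n_adapt = 500, n_keep = 5000, seed = 1, init = NULL,
                      include_likelihood = TRUE, prop_scale = list()) {
  stopifnot(inherits(cov, "phylo_cov"), inherits(spec, "model_spec"))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n || length(cov$taxa) != n)
    stop("y, X and cov dimensions disagree")
  default_init <- list(theta = setNames(numeric(p), colnames(X)),
                       u = numeric(n), gamma = 1, lambda = 0.5)
  if (include_likelihood)
    default_init$theta[1] <- qlogis(mean(y))
  init <- utils::modifyList(default_init, as.list(init %||% list()))
  ps <- utils::modifyList(list(theta = 0.5, u = 0.5, gamma = 0.5,
                               lambda = 0.1), as.list(prop_scale))
  lp0 <- cpp_model_logpost(y, X, cov$C, init$theta, init$u, init$gamma,
                           init$lambda, spec$prior_coef_sd, spec$gamma_shape,
                           spec$gamma_rate, spec$lambda_max,
                           include_likelihood)
  if (!is.finite(lp0)) stop("log posterior not finite at the initial state")
  par_names <- c(colnames(X), paste0("u[", cov$taxa, "]"), "gamma", "lambda")
  seeds <- .chain_seeds(seed, n_chains)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seeds[ch])
    res <- cpp_mwg_chain(y, X, cov$C, spec$prior_coef_sd, spec$gamma_shape,
                         spec$gamma_rate, spec$lambda_max, n_adapt, n_keep,
                         include_likelihood, init$theta, init$u, init$gamma,
                         init$lambda, rep_len(ps$theta, p), rep_len(ps$u, n),
                         ps$gamma, ps$lambda)
    M <- res$draws
    colnames(M) <- par_names
    chains[[ch]] <- M
  }
  .new_chain_set(chains, n_adapt, n_keep, seed, par_names,
                 extra = list(spec = spec, n_taxa = n,
                              coef_names = colnames(X)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write chains as CSV
#'
#' One row per draw with \code{chain} and \code{iteration} columns followed
#' by one column per parameter.
#'
#' @param chains a \code{"chain_set"}.
#' @param file output path.
#' @export
write_chains <- function(chains, file) {
  stopifnot(inherits(chains, "chain_set"))
  rows <- lapply(seq_along(chains$chains), function(ch) {
    M <- chains$chains[[ch]]
    data.frame(chain = ch, iteration = seq_len(nrow(M)), M,
               check.names = FALSE)
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
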