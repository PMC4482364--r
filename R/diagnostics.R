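# Convergence diagnostics and posterior interval summaries: split-chain
# Gelman-Rubin, autocorrelation, effective sample size, HPD intervals and
# Monte Carlo standard errors.

#' Sample autocorrelation function
#'
#' Lag-k sample autocorrelations with the biased (n-denominator) estimator;
#' \code{rho[1]} is lag 0 and always 1.
#'
#' @param draws numeric vector.
#' @param max_lag largest lag, must be below \code{length(draws) / 2}.
#' @return numeric vector of length \code{max_lag + 1} (lags 0..max_lag).
#' @export
autocorrelation <- function(draws, max_lag) {
  n <- length(draws)
  if (max_lag >= n / 2) stop("max_lag must be < n/2")
  drop(acf(draws, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
}

#' Effective sample size of an autocorrelated chain
#'
#' ESS = n / (1 + 2 * sum(rho_k)) with the autocorrelation sum truncated by
#' the initial-positive-sequence rule: summation stops just before the first
#' lag k at which rho_k + rho_(k+1) <= 0. The result is capped at n. A
#' constant chain returns 1 with attribute \code{degenerate = TRUE}.
#'
#' @param draws numeric vector of at least 10 draws (chains already
#'   combined, as inference is based on the concatenated chain).
#' @return scalar ESS.
#' @export
effective_sample_size <- function(draws) {
  n <- length(draws)
  if (n < 10) stop("need at least 10 draws")
  if (var(draws) == 0)
    return(structure(1, degenerate = TRUE))
  max_lag <- min(n %/% 2 - 1, 2000L)
  rho <- autocorrelation(draws, max_lag)[-1]  # lags 1..max_lag
  K <- length(rho)
  cut <- K
  for (k in seq_len(K - 1)) {
    if (rho[k] + rho[k + 1] <= 0) { cut <- k - 1; break }
  }
  s <- if (cut >= 1) sum(rho[seq_len(cut)]) else 0
  min(n, max(1, n / (1 + 2 * s)))
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Each chain is split in half and the potential scale reduction factor
#' R-hat = sqrt(((n - 1)/n * W + B/n) / W) is computed over the split
#' halves, where W is the mean within-half variance and B the between-half
#' variance of the half means (times n). Splitting makes the statistic
#' sensitive to within-chain trends. If every half has zero variance the
#' diagnostic is undefined and \code{NA} is returned with attribute
#' \code{degenerate = TRUE}.
#'
#' @param chains list of numeric vectors (one per chain, equal lengths,
#'   at least 2 chains of at least 4 draws), or a \code{"chain_set"} with
#'   \code{parameter} naming a column.
#' @param parameter column name when \code{chains} is a chain set.
#' @return scalar R-hat.
#' @export
gelman_rubin <- function(chains, parameter = NULL) {
  if (inherits(chains, "chain_set"))
    chains <- lapply(chains$chains, function(M) M[, parameter])
  stopifnot(is.list(chains), length(chains) >= 2)
  len <- unique(vapply(chains, length, 1L))
  if (length(len) != 1 || len < 4) stop("chains must share a length >= 4")
  half <- len %/% 2
  halves <- unlist(lapply(chains, function(x)
    list(x[seq_len(half)], x[seq_len(half) + (len - half)])),
    recursive = FALSE)
  n <- half
  W <- mean(vapply(halves, var, 0))
  if (W == 0) return(structure(NA_real_, degenerate = TRUE))
  B <- n * var(vapply(halves, mean, 0))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval of the sorted draws containing
#' \code{ceiling(mass * n)} draws; width ties are broken toward the lower
#' start.
#'
#' @param draws numeric vector of at least 20 draws.
#' @param mass interval mass in (0, 1), default 0.95.
#' @return numeric vector \code{c(lower, upper)}.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  n <- length(draws)
  if (n < 20) stop("need at least 20 draws")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  s <- sort(draws)
  m <- ceiling(mass * n)
  starts <- seq_len(n - m + 1)
  widths <- s[starts + m - 1] - s[starts]
  # ties (up to floating-point noise) break toward the lower start
  tol <- 1e-9 * (s[n] - s[1])
  i <- which(widths <= min(widths) + tol)[1]
  c(s[i], s[i + m - 1])
}

#' Monte Carlo standard error of the posterior mean
#'
#' sd(draws) / sqrt(ESS). A degenerate (constant) chain returns 0 with
#' attribute \code{degenerate = TRUE}.
#'
#' @param draws numeric vector (combined chain).
#' @return scalar standard error.
#' @export
mcse <- function(draws) {
  if (var(draws) == 0) return(structure(0, degenerate = TRUE))
  sd(draws) / sqrt(effective_sample_size(draws))
}
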