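# Reporting surfaces: posterior summary tables with notable-effect flags,
# decline tabulations by region and genus, and regional descriptive
# statistics.

#' Summarise a posterior sample
#'
#' One row per parameter with the posterior mean, posterior sd, Monte Carlo
#' standard error of the mean (\code{mcse}; chains are concatenated first,
#' and the reported \code{ess} is computed on that combined sequence), the
#' 95\% highest posterior density interval, the split-chain Gelman-Rubin
#' statistic, and flags: \code{notable} is \code{TRUE} when the HPD interval
#' excludes zero, evaluated for regression coefficients only; the dispersion
#' \code{gamma} and signal \code{lambda} are positive-support model
#' parameters for which a sign test is meaningless, so their \code{notable}
#' is \code{NA} and they are always \code{starred} as reported rows (as are
#' notable coefficients).
#'
#' @param chains a \code{"chain_set"} from [fit_model()] (or any chain set).
#' @param prob HPD interval mass, default 0.95.
#' @param include_random include the per-taxon \code{u[...]} rows
#'   (default \code{FALSE}, matching the reported tables).
#' @return a data.frame of class \code{"posterior_summary"}.
#' @export
summarize_posterior <- function(chains, prob = 0.95, include_random = FALSE) {
  stopifnot(inherits(chains, "chain_set"))
  if (!length(chains$chains) || !nrow(chains$chains[[1]]))
    stop("empty chains")
  M <- combine_chains(chains)
  pars <- colnames(M)
  if (!include_random) pars <- pars[!grepl("^u\\[", pars)]
  model_par <- pars %in% c("gamma", "lambda")
  rows <- lapply(pars, function(pn) {
    x <- M[, pn]
    hpd <- hpd_interval(x, prob)
    rhat <- gelman_rubin(chains, pn)
    data.frame(parameter = pn, mean = mean(x), sd = sd(x),
               mcse = as.numeric(mcse(x)),
               hpd_lower = hpd[1], hpd_upper = hpd[2],
               ess = as.numeric(effective_sample_size(x)),
               rhat = as.numeric(rhat), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  excl0 <- out$hpd_lower > 0 | out$hpd_upper < 0
  out$notable <- ifelse(model_par[match(out$parameter, pars)], NA, excl0)
  out$starred <- model_par[match(out$parameter, pars)] | (excl0 &
    !model_par[match(out$parameter, pars)])
  rownames(out) <- NULL
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' @export
print.posterior_summary <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$mean <- round(y$mean, digits)
  y$mcse <- signif(y$mcse, 2)
  y$`95% HPDI` <- sprintf("(%.*f, %.*f)", digits, y$hpd_lower, digits,
                          y$hpd_upper)
  y$` ` <- ifelse(y$starred, "*", "")
  print(y[, c("parameter", "mean", "mcse", "95% HPDI", "ess", "rhat", " ")],
        row.names = FALSE)
  invisible(x)
}

#' Tabulate declines by region and category
#'
#' Counts of analysis taxa per region in the decline categories of
#' [categorize_decline()], with row totals; the grand total equals the
#' number of rows in the table.
#'
#' @param table a \code{"trait_table"} with regions assigned.
#' @return a data.frame (one row per region plus columns
#'   \code{None, Low, Moderate, High, Total}) of class
#'   \code{"decline_tabulation"}.
#' @export
tabulate_declines <- function(table) {
  regions <- c("north", "south")
  cats <- c("None", "Low", "Moderate", "High")
  counts <- matrix(0L, 2, 4, dimnames = list(regions, cats))
  if (nrow(table)) {
    cat_f <- categorize_decline(table$decline)
    tab <- table(factor(table$region, regions), cat_f)
    counts[rownames(tab), colnames(tab)] <- tab
  }
  out <- data.frame(region = c("Northern region", "Southern region"),
                    counts, Total = rowSums(counts), check.names = FALSE,
                    row.names = NULL)
  class(out) <- c("decline_tabulation", "data.frame")
  out
}

#' Incidence of decline within genera
#'
#' Counts declining (decline > 0 in any region) versus stable species per
#' genus. Species present in both regions are counted once; a species is
#' declining if it declined in either region. Empty genus labels are grouped
#' under \code{"unknown"} with a warning.
#'
#' @param table a \code{"trait_table"}.
#' @return data.frame with columns \code{genus}, \code{n_declining},
#'   \code{n_stable}.
#' @export
genus_incidence <- function(table) {
  genus <- as.character(table$genus)
  if (any(is.na(genus) | !nzchar(genus))) {
    warning("empty genus labels grouped under 'unknown'")
    genus[is.na(genus) | !nzchar(genus)] <- "unknown"
  }
  per_species <- aggregate(list(declining = table$decline > 0),
                           by = list(genus = genus, species = table$species),
                           FUN = any)
  agg <- aggregate(list(n_declining = per_species$declining),
                   by = list(genus = per_species$genus), FUN = sum)
  size <- aggregate(list(n = per_species$declining),
                    by = list(genus = per_species$genus), FUN = length)
  out <- merge(agg, size, by = "genus")
  out$n_stable <- out$n - out$n_declining
  out$n <- NULL
  out[order(out$genus), , drop = FALSE]
}

#' Regional descriptive statistics of female body mass
#'
#' Arithmetic mean (raw grams, not log) and standard error of female mass
#' per region, with the number of taxa contributing. A region with fewer
#' than two mass values has its SE reported as \code{NA}.
#'
#' @param table a \code{"trait_table"}.
#' @return data.frame with columns \code{region}, \code{mean_mass_g},
#'   \code{se_mass_g}, \code{n}.
#' @export
regional_descriptives <- function(table) {
  out <- do.call(rbind, lapply(c("north", "south"), function(r) {
    m <- table$female_mass_g[table$region == r & !is.na(table$female_mass_g)]
    data.frame(region = r, mean_mass_g = if (length(m)) mean(m) else NA_real_,
               se_mass_g = if (length(m) >= 2) sd(m) / sqrt(length(m))
                           else NA_real_,
               n = length(m))
  }))
  rownames(out) <- NULL
  out
}

#' Binned decline summaries for plotting
#'
#' Mean proportional decline (and taxon counts) by region within bins of a
#' chosen predictor: pre-decline range size classes (log10-width bins) or
#' habitat-openness ranks.
#'
#' @param table a \code{"trait_table"}.
#' @param by \code{"range"} or \code{"habitat"}.
#' @return data.frame with \code{region}, \code{bin}, \code{n},
#'   \code{mean_decline}.
#' @export
binned_decline_summary <- function(table, by = c("range", "habitat")) {
  by <- match.arg(by)
  bin <- if (by == "range") {
    cut(log10(table$range_km2),
        breaks = seq(floor(min(log10(table$range_km2))),
                     ceiling(max(log10(table$range_km2))), by = 1))
  } else {
    factor(table$habitat_openness, 0:4)
  }
  agg <- aggregate(list(mean_decline = table$decline),
                   by = list(region = table$region, bin = bin), FUN = mean)
  n <- aggregate(list(n = table$decline),
                 by = list(region = table$region, bin = bin), FUN = length)
  merge(agg, n, by = c("region", "bin"))[, c("region", "bin", "n",
                                             "mean_decline")]
}
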