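# Synthetic data with the exact statistical structure the model assumes:
# Yule trees, trait tables with region duplication, and beta-distributed
# decline responses over phylogenetically correlated species effects.

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the structure of the Australian-rodent study: about 60
#' species, roughly an eighth of which straddle the regional boundary and
#' enter both regions; log-normal range sizes, rainfall, female masses and
#' litter sizes on realistic scales; an ordinal habitat-openness rank
#' weighted toward open habitats; and true parameter values echoing the
#' magnitudes of the fitted main-effects model (intercept -1.66, region
#' effect 1.22, log-range effect -0.45, habitat-openness effect -0.61,
#' dispersion 0.5, lambda 0.8).
#'
#' @param n_species number of species (tree tips).
#' @param p_straddle probability a species is present in both regions.
#' @param birth_rate Yule (pure-birth) speciation rate.
#' @param true_theta named coefficient vector on the standardised predictor
#'   scale; names must match design-matrix columns.
#' @param true_gamma true beta dispersion.
#' @param true_lambda true Pagel's lambda.
#' @param predictors list of log-normal (meanlog, sdlog) parameters for
#'   \code{range_km2}, \code{rainfall_mm}, \code{female_mass_g},
#'   \code{litter_size}, and \code{habitat_weights} over ranks 0..4.
#' @param seed master seed for [simulate_dataset()].
#' @return a list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_species = 60, p_straddle = 8 / 61,
                             birth_rate = 1,
                             true_theta = c("Intercept" = -1.66, "NS" = 1.22,
                                            "log Range" = -0.45,
                                            "log Female mass" = 0,
                                            "log Rainfall" = 0,
                                            "Habitat openness" = -0.61,
                                            "log Litter" = 0),
                             true_gamma = 0.5, true_lambda = 0.8,
                             predictors = list(
                               range_km2 = c(meanlog = 12, sdlog = 1.5),
                               rainfall_mm = c(meanlog = log(600), sdlog = 0.5),
                               female_mass_g = c(meanlog = log(60), sdlog = 0.9),
                               litter_size = c(meanlog = log(3.5), sdlog = 0.3),
                               habitat_weights = c(0.30, 0.25, 0.20, 0.15, 0.10)),
                             seed = 1) {
  stopifnot(n_species >= 2, p_straddle >= 0, p_straddle <= 1,
            birth_rate > 0, true_gamma > 0,
            true_lambda >= 0, true_lambda <= 1.2)
  structure(list(n_species = n_species, p_straddle = p_straddle,
                 birth_rate = birth_rate, true_theta = true_theta,
                 true_gamma = true_gamma, true_lambda = true_lambda,
                 predictors = predictors, seed = seed),
            class = "synthetic_config")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation: starting from a single stem lineage, with k extant
#' lineages the next speciation occurs after an Exponential(k * birth_rate)
#' waiting time and splits a uniformly chosen lineage; after the n-th
#' lineage appears a final Exponential(n * birth_rate) interval elapses
#' before the present. The tree is ultrametric by construction; the stem
#' interval is kept as the root edge.
#'
#' @param n number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed optional seed; when given the tree is a deterministic
#'   function of it.
#' @return a \code{"phylo"} object with tips \code{t1..tn}.
#' @export
simulate_yule_tree <- function(n, birth_rate = 1, seed = NULL) {
  if (n < 2) stop("need n >= 2 tips")
  stopifnot(birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  # lineage records: birth time, split time (NA while extant), children
  birth <- 0
  split_t <- NA_real_
  kids <- list(NULL)
  active <- 1L
  t_now <- 0
  while (length(active) < n) {
    k <- length(active)
    t_now <- t_now + rexp(1, k * birth_rate)
    sp <- active[sample.int(k, 1)]
    ids <- length(birth) + 1:2
    birth <- c(birth, t_now, t_now)
    split_t <- c(split_t, NA_real_, NA_real_)
    split_t[sp] <- t_now
    kids[ids] <- list(NULL)
    kids[[sp]] <- ids
    active <- c(setdiff(active, sp), ids)
  }
  t_end <- t_now + rexp(1, n * birth_rate)
  tip_counter <- 0L
  as_newick <- function(id) {
    if (is.null(kids[[id]])) {
      tip_counter <<- tip_counter + 1L
      sprintf("t%d:%.10g", tip_counter, t_end - birth[id])
    } else {
      sprintf("(%s,%s):%.10g", as_newick(kids[[id]][1]),
              as_newick(kids[[id]][2]), split_t[id] - birth[id])
    }
  }
  # record 1's interval from the origin to the first split is the stem,
  # stored by ape as root.edge
  ape::read.tree(text = paste0(as_newick(1L), ";"))
}

# genus labels = maximal clades whose root crosses a cut depth
.genus_labels <- function(tree, cut_frac = 0.5) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  cut <- cut_frac * max(depth[seq_len(n)])
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1L
  lab <- character(n)
  for (i in seq_len(n)) {
    node <- i
    while (node != root && parent[node] != 0L && depth[parent[node]] >= cut)
      node <- parent[node]
    lab[i] <- paste0("G", node)
  }
  setNames(lab, tree$tip.label)
}

#' Simulate a trait table over a tree
#'
#' Draws the model predictors for every species: log-normal range size,
#' rainfall, female mass and litter size, a categorical habitat-openness
#' rank, and a region (each species is placed in both regions with
#' probability \code{p_straddle}, else in one at random). Genus labels are
#' the maximal clades below half the tree height. Range-centroid latitudes
#' consistent with the assigned region are attached. The decline response is
#' left \code{NA} until [simulate_responses()].
#'
#' @param tree a \code{"phylo"} (tips become species).
#' @param config a \code{"synthetic_config"}.
#' @param seed optional seed.
#' @return a \code{"trait_table"} (with \code{decline} all \code{NA}).
#' @export
simulate_traits <- function(tree, config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  sp <- tree$tip.label
  n <- length(sp)
  pr <- config$predictors
  draw_ln <- function(par) rlnorm(n, par[["meanlog"]], par[["sdlog"]])
  genus <- .genus_labels(tree)[sp]
  base <- data.frame(
    species = sp, genus = genus,
    range_km2 = draw_ln(pr$range_km2),
    rainfall_mm = draw_ln(pr$rainfall_mm),
    female_mass_g = draw_ln(pr$female_mass_g),
    habitat_openness = sample(0:4, n, replace = TRUE,
                              prob = pr$habitat_weights),
    litter_size = draw_ln(pr$litter_size),
    stringsAsFactors = FALSE)
  straddle <- runif(n) < config$p_straddle
  solo_region <- ifelse(runif(n) < 0.5, "north", "south")
  rows <- lapply(seq_len(n), function(i) {
    regs <- if (straddle[i]) c("north", "south") else solo_region[i]
    df <- base[rep(i, length(regs)), , drop = FALSE]
    df$region <- regs
    df
  })
  df <- do.call(rbind, rows)
  df$centroid_latitude <- ifelse(df$region == "north",
                                 runif(nrow(df), -23.4, -12),
                                 runif(nrow(df), -38, -23.5))
  df$decline <- NA_real_
  df$taxon_id <- ifelse(df$species %in% df$species[duplicated(df$species)],
                        paste(df$species, df$region, sep = "_"), df$species)
  rownames(df) <- NULL
  structure(df, provenance = "synthetic",
            class = c("trait_table", "data.frame"))
}

#' Simulate beta-distributed decline responses
#'
#' Draws species effects u ~ MVN(0, C_lambda(true_lambda)), forms the
#' logit-linear mean mu = plogis(X theta + u) over the standardised design,
#' and draws decline ~ Beta(mu * gamma, (1 - mu) * gamma).
#'
#' @param table a \code{"trait_table"} (decline may be \code{NA}).
#' @param cov a \code{"phylo_cov"} over \code{table$taxon_id} (base matrix).
#' @param config a \code{"synthetic_config"} providing the true parameters.
#' @param seed optional seed.
#' @return \code{table} with \code{decline} filled in; the true species
#'   effects are attached as attribute \code{"true_u"}.
#' @export
simulate_responses <- function(table, cov, config, seed = NULL) {
  stopifnot(inherits(table, "trait_table"), inherits(cov, "phylo_cov"),
            inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  if (!identical(cov$taxa, table$taxon_id))
    stop("covariance taxa do not match table taxon_id")
  std <- .standardize_predictors(table)
  X <- cbind(Intercept = 1, as.matrix(std$predictors))
  colnames(X) <- .main_effect_columns
  theta <- config$true_theta
  if (!all(names(theta) %in% colnames(X)))
    stop("true_theta names must match main-effects design columns")
  eta_fix <- drop(X[, names(theta), drop = FALSE] %*% theta)
  CL <- cov$C * config$true_lambda
  diag(CL) <- diag(cov$C)
  R <- tryCatch(chol(CL), error = function(e)
    stop("C_lambda not positive definite at true_lambda"))
  u <- drop(crossprod(R, rnorm(nrow(X))))
  mu <- plogis(eta_fix + u)
  y <- rbeta(nrow(X), mu * config$true_gamma, (1 - mu) * config$true_gamma)
  # guard against floating-point underflow to the boundary (tiny-shape beta
  # draws can round to 0 or 1 in double precision)
  table$decline <- pmin(pmax(y, .Machine$double.xmin), 1 - 1e-12)
  attr(table, "true_u") <- u
  table
}

#' Simulate a complete dataset bundle
#'
#' Tree, traits and responses from one master seed; optionally written to a
#' directory as \code{tree.nwk}, \code{traits.csv} and \code{truth.json}
#' (true parameters plus the seed) for a downstream fit.
#'
#' @param config a \code{"synthetic_config"}.
#' @param out optional output directory.
#' @return list with \code{tree}, \code{table}, \code{cov} (base expanded
#'   covariance), \code{true_u}, \code{config}.
#' @export
simulate_dataset <- function(config = synthetic_config(), out = NULL) {
  set.seed(config$seed)
  tree <- simulate_yule_tree(config$n_species, config$birth_rate)
  table <- simulate_traits(tree, config)
  mapping <- setNames(table$species, table$taxon_id)
  cov <- expand_duplicated_taxa(phylo_vcv(tree), mapping)
  table <- simulate_responses(table, cov, config)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_newick(tree, file.path(out, "tree.nwk"))
    write.csv(as.data.frame(table), file.path(out, "traits.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(true_theta = as.list(config$true_theta),
           true_gamma = config$true_gamma,
           true_lambda = config$true_lambda, seed = config$seed),
      file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(tree = tree, table = table, cov = cov,
       true_u = attr(table, "true_u"), config = config)
}

#' Parameter-recovery experiment
#'
#' For each replicate: simulate a dataset from \code{config}, fit the model,
#' and record whether each true coefficient (and gamma, lambda) lies inside
#' its 95\% HPD interval, the posterior-mean error, and the worst
#' split-chain R-hat. Replicates with any R-hat above 1.1 are flagged as
#' non-converged but still reported.
#'
#' @param config a \code{"synthetic_config"}.
#' @param n_replicates number of simulate-fit cycles.
#' @param n_chains,n_adapt,n_keep sampler settings per fit.
#' @param seed master seed; replicate seeds derive from it.
#' @param form model form to fit.
#' @param squeeze response-compression rule passed to
#'   [prepare_predictors()]; synthetic beta draws are already strictly
#'   inside (0, 1), so the default is \code{"none"}.
#' @return list of class \code{"recovery_report"}: \code{coverage} (per
#'   parameter: covered count, replicate count, RMSE of the posterior mean),
#'   \code{replicates} (long data.frame), \code{n_converged}.
#' @export
recovery_experiment <- function(config = synthetic_config(),
                                n_replicates = 20, n_chains = 4,
                                n_adapt = 500, n_keep = 5000, seed = 1,
                                form = "main_effects", squeeze = "none") {
  seeds <- .chain_seeds(seed, n_replicates)
  truth <- c(config$true_theta, gamma = config$true_gamma,
             lambda = config$true_lambda)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seeds[r]
    dat <- simulate_dataset(cfg)
    prep <- prepare_predictors(dat$table, squeeze = squeeze)
    spec <- model_spec(form = form, squeeze = squeeze)
    X <- build_design(prep, spec)
    fit <- fit_model(prep$y, X, dat$cov, spec, n_chains = n_chains,
                     n_adapt = n_adapt, n_keep = n_keep, seed = seeds[r])
    sm <- summarize_posterior(fit)
    sm <- sm[sm$parameter %in% names(truth), , drop = FALSE]
    tr <- truth[sm$parameter]
    reps[[r]] <- data.frame(replicate = r, parameter = sm$parameter,
                            truth = as.numeric(tr), mean = sm$mean,
                            hpd_lower = sm$hpd_lower,
                            hpd_upper = sm$hpd_upper,
                            covered = tr >= sm$hpd_lower &
                                      tr <= sm$hpd_upper,
                            max_rhat = max(sm$rhat, na.rm = TRUE),
                            converged = max(sm$rhat, na.rm = TRUE) <= 1.1,
                            stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, reps)
  coverage <- do.call(rbind, lapply(split(long, long$parameter), function(d)
    data.frame(parameter = d$parameter[1], n_covered = sum(d$covered),
               n_replicates = nrow(d),
               rmse = sqrt(mean((d$mean - d$truth)^2)))))
  rownames(coverage) <- NULL
  structure(list(coverage = coverage, replicates = long,
                 n_converged = sum(vapply(split(long, long$replicate),
                                          function(d) all(d$converged), TRUE))),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery over %d replicates (%d converged):\n",
              max(x$replicates$replicate), x$n_converged))
  print(x$coverage, row.names = FALSE)
  invisible(x)
}
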