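test_that("Yule simulation produces valid ultrametric trees deterministically", {
  t2 <- simulate_yule_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  d2 <- ape::node.depth.edgelength(t2)[1:2]
  expect_equal(d2[1], d2[2], tolerance = 1e-9)  # a single cherry

  a <- write_newick(simulate_yule_tree(25, seed = 5))
  b <- write_newick(simulate_yule_tree(25, seed = 5))
  expect_identical(a, b)
  expect_false(identical(a, write_newick(simulate_yule_tree(25, seed = 6))))
  expect_error(simulate_yule_tree(1), "n >= 2")

  tr <- simulate_yule_tree(40, seed = 8)
  depths <- ape::node.depth.edgelength(tr)[seq_len(40)]
  expect_lt(diff(range(depths)), 1e-8)        # ultrametric
  expect_true(all(tr$edge.length >= 0))
})

test_that("mean origin-to-tip depth matches the pure-birth expectation", {
  # with k lineages the wait is Exp(k b); total depth (stem included) has
  # expectation 1/b + sum_{k=2..n} 1/(k b)
  n <- 50; b <- 1; reps <- 1000
  expected <- 1 / b + sum(1 / (2:n * b))
  depths <- vapply(seq_len(reps), function(r) {
    tr <- simulate_yule_tree(n, b, seed = 10000 + r)
    tr$root.edge + max(ape::node.depth.edgelength(tr))
  }, 0)
  expect_equal(mean(depths), expected, tolerance = 0.05)
})

test_that("trait simulation honours straddling probabilities and supports", {
  tree <- simulate_yule_tree(30, seed = 3)
  cfg0 <- synthetic_config(n_species = 30, p_straddle = 0)
  t0 <- simulate_traits(tree, cfg0, seed = 4)
  expect_equal(nrow(t0), 30L)
  cfg1 <- synthetic_config(n_species = 30, p_straddle = 1)
  t1 <- simulate_traits(tree, cfg1, seed = 4)
  expect_equal(nrow(t1), 60L)
  expect_true(all(table(t1$species) == 2))
  expect_setequal(unique(t1$region), c("north", "south"))

  # distribution supports over a large draw
  big_tree <- simulate_yule_tree(400, seed = 9)
  big <- simulate_traits(big_tree, synthetic_config(n_species = 400), seed = 10)
  expect_true(all(big$female_mass_g > 0))
  expect_true(all(big$range_km2 > 0))
  expect_true(all(big$litter_size > 0))
  expect_true(all(big$habitat_openness %in% 0:4))
  # latitudes agree with assigned regions
  expect_identical(assign_region(big$centroid_latitude), big$region)
})

test_that("response simulation follows the generative model", {
  dat <- random_dataset(n_species = 12, seed = 21)
  expect_true(all(dat$table$decline > 0 & dat$table$decline < 1))

  # determinism
  d2 <- random_dataset(n_species = 12, seed = 21)
  expect_identical(dat$table$decline, d2$table$decline)

  # huge dispersion: y pinned to mu
  cfg <- synthetic_config(n_species = 12, true_gamma = 1e6, seed = 22)
  tree <- simulate_yule_tree(12, seed = 22)
  tab <- simulate_traits(tree, cfg, seed = 23)
  cov <- expand_duplicated_taxa(phylo_vcv(tree),
                                setNames(tab$species, tab$taxon_id))
  out <- simulate_responses(tab, cov, cfg, seed = 24)
  std <- phylobeta:::.standardize_predictors(out)
  X <- cbind(1, as.matrix(std$predictors))
  mu <- plogis(drop(X %*% cfg$true_theta) + attr(out, "true_u"))
  expect_true(all(abs(out$decline - mu) < 0.01))
})

test_that("simulated responses obey the beta mean identity", {
  # mu fixed at 0.3 (intercept only, species effects disabled by a
  # near-zero covariance); pooled draws across seeds give 50000 samples
  n <- 50; reps <- 1000
  cfg <- synthetic_config(
    n_species = n, p_straddle = 0, true_gamma = 0.5,
    true_theta = c("Intercept" = qlogis(0.3), "NS" = 0, "log Range" = 0,
                   "log Female mass" = 0, "log Rainfall" = 0,
                   "Habitat openness" = 0, "log Litter" = 0))
  tree <- simulate_yule_tree(n, seed = 31)
  tab <- simulate_traits(tree, cfg, seed = 32)
  C <- diag(1e-12, n)
  dimnames(C) <- list(tab$taxon_id, tab$taxon_id)
  cov <- as_phylo_cov(C)
  draws <- unlist(lapply(seq_len(reps), function(r)
    simulate_responses(tab, cov, cfg, seed = 40000 + r)$decline))
  expect_equal(length(draws), n * reps)
  expect_lt(abs(mean(draws) - 0.3), 0.005)
})

test_that("dataset bundles are reproducible end to end and written to disk", {
  cfg <- synthetic_config(n_species = 10, seed = 77)
  out <- withr::local_tempdir()
  d1 <- simulate_dataset(cfg, out = out)
  expect_true(all(file.exists(file.path(out, c("tree.nwk", "traits.csv",
                                               "truth.json")))))
  truth <- jsonlite::read_json(file.path(out, "truth.json"))
  expect_equal(truth$true_lambda, cfg$true_lambda)
  d2 <- simulate_dataset(cfg)
  expect_identical(write_newick(d1$tree), write_newick(d2$tree))
  expect_identical(d1$table$decline, d2$table$decline)
  expect_identical(d1$cov$C, d2$cov$C)
  # covariance rows align with the table, duplicates share tips
  expect_identical(d1$cov$taxa, d1$table$taxon_id)
})

test_that("a short recovery experiment reports coverage per parameter", {
  cfg <- synthetic_config(n_species = 20)
  rep <- recovery_experiment(cfg, n_replicates = 2, n_chains = 2,
                             n_adapt = 200, n_keep = 600, seed = 12)
  expect_s3_class(rep, "recovery_report")
  expect_setequal(rep$coverage$parameter,
                  c(names(cfg$true_theta), "gamma", "lambda"))
  expect_true(all(rep$coverage$n_replicates == 2))
  expect_true(all(rep$coverage$n_covered <= 2))
  expect_true(all(is.finite(rep$coverage$rmse)))
  expect_equal(nrow(rep$replicates), 2 * 9)
})
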