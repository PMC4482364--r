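# Shared fixtures, built in code at test time.

# small trait table with known declines and regions
toy_trait_table <- function() {
  as_trait_table(data.frame(
    species = c("Notomys alpha", "Pseudomys beta", "Rattus gamma",
                "Pseudomys delta"),
    region = c("north", "north", "north", "south"),
    decline = c(0, 0.1, 0.6, 0.3),
    range_km2 = c(1e5, 2e5, 5e4, 3e5),
    rainfall_mm = c(400, 800, 1200, 600),
    female_mass_g = c(30, 45, 150, 60),
    habitat_openness = c(0, 1, 4, 2),
    litter_size = c(3, 4, 5, 3.5),
    stringsAsFactors = FALSE))
}

# random trait table over a simulated tree, responses filled in
random_dataset <- function(n_species = 12, seed = 1, ...) {
  simulate_dataset(synthetic_config(n_species = n_species, seed = seed, ...))
}

# brute-force phylogenetic covariance: for each pair of tips, enumerate the
# root-to-tip paths and sum the branch lengths they share
brute_force_vcv <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_edges <- function(tip) {       # vector of node ids whose parent edge
    out <- integer(0)                 # lies on the root-to-tip path
    node <- tip
    while (parent[node] != 0L) {
      out <- c(out, node)
      node <- parent[node]
    }
    out
  }
  paths <- lapply(seq_len(n), path_edges)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n))
    for (j in seq_len(n))
      C[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
  C
}

# exhaustive-window HPD search, independent of hpd_interval(); width ties
# (up to float noise relative to the draw spread) keep the lowest window
brute_force_hpd <- function(draws, mass = 0.95) {
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(mass * n)
  tol <- 1e-9 * (s[n] - s[1])
  best <- c(s[1], s[m])
  for (i in seq_len(n - m + 1)) {
    if (s[i + m - 1] - s[i] < best[2] - best[1] - tol)
      best <- c(s[i], s[i + m - 1])
  }
  best
}

# wrap a plain matrix as a phylo_cov (for direct density checks)
as_phylo_cov <- function(C) {
  structure(list(taxa = rownames(C) %||% paste0("x", seq_len(nrow(C))),
                 C = C, lambda = NULL, C_lambda = NULL,
                 positive_definite = TRUE),
            class = "phylo_cov")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
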