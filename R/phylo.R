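# Phylogeny ingestion and phylogenetic covariance construction.

#' Read a rooted Newick tree
#'
#' Parses a Newick string (or a file containing one) into an \code{ape}
#' \code{"phylo"} object after validating the basic grammar. Validation
#' reports the character position of unbalanced parentheses and of a missing
#' terminating semicolon, and rejects duplicate or empty tip labels. Internal
#' node labels are dropped with a warning; a root edge length is kept when
#' present.
#'
#' @param text a Newick string, or the path of a file whose first
#'   non-empty line is one.
#' @return an object of class \code{"phylo"}.
#' @seealso [write_newick()], [phylo_vcv()]
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("[();]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  .validate_newick(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse failed")
  if (!is.null(tree$node.label) && any(nzchar(tree$node.label))) {
    warning("internal node labels present; ignored")
    tree$node.label <- NULL
  }
  .validate_phylo(tree)
  tree
}

# Grammar checks with character positions, ahead of the real parser.
.validate_newick <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("unbalanced ')' at character %d", i))
    }
  }
  if (depth > 0L)
    stop(sprintf("unclosed '(' (depth %d) at end of string, character %d",
                 depth, length(chars)))
  semi <- regexpr(";", text, fixed = TRUE)
  if (semi < 0L)
    stop(sprintf("missing ';' terminator at character %d", nchar(text) + 1L))
  invisible(TRUE)
}

.validate_phylo <- function(tree) {
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip label")
  if (anyDuplicated(labs))
    stop("duplicate tip labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths")
  tip_edges <- tree$edge[, 2] <= length(labs)
  if (any(is.na(tree$edge.length[tip_edges])))
    stop("tip branch length missing")
  invisible(TRUE)
}

#' Write a tree as Newick
#'
#' @param tree a \code{"phylo"} object.
#' @param file optional path; when omitted the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Phylogenetic variance-covariance matrix
#'
#' Builds the matrix C whose entry (i, j) is the summed branch length from
#' the root to the most recent common ancestor of tips i and j; the diagonal
#' holds root-to-tip distances. This is the covariance of a Brownian-motion
#' trait evolved along the tree. A root edge, if present, is not counted.
#'
#' @param tree a \code{"phylo"} object.
#' @param order character vector of tip labels giving the row/column order;
#'   defaults to the tree's tip order. Every name must be a tip of
#'   \code{tree}.
#' @return an object of class \code{"phylo_cov"}: a list with elements
#'   \code{taxa} (labels), \code{C} (the matrix), and \code{lambda},
#'   \code{C_lambda} (filled in by [lambda_transform()]).
#' @export
phylo_vcv <- function(tree, order = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (is.null(order)) order <- tree$tip.label
  missing <- setdiff(order, tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  depth <- ape::node.depth.edgelength(tree)  # distance from root, all nodes
  mrca <- ape::mrca(tree)                    # n x n node ids, labelled
  C <- matrix(depth[mrca], n, n, dimnames = dimnames(mrca))
  diag(C) <- depth[seq_len(n)]
  C <- C[order, order, drop = FALSE]
  structure(list(taxa = order, C = C, lambda = NULL, C_lambda = NULL,
                 positive_definite = TRUE),
            class = "phylo_cov")
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat(sprintf("Phylogenetic covariance over %d taxa", length(x$taxa)))
  if (!is.null(x$lambda))
    cat(sprintf("; lambda = %.4g%s", x$lambda,
                if (isTRUE(x$positive_definite)) "" else " (not PD)"))
  cat("\n")
  invisible(x)
}

#' Pagel's lambda transformation
#'
#' Multiplies every off-diagonal entry of the phylogenetic covariance matrix
#' by \code{lam}, leaving the diagonal untouched. \code{lam = 1} returns the
#' Brownian-motion covariance; \code{lam = 0} the star phylogeny (independent
#' tips). Values of \code{lam} up to 1.2 are admitted (the prior support used
#' in model fitting); for \code{lam > 1} the result can lose positive
#' definiteness, which is flagged rather than silently accepted.
#'
#' @param cov a \code{"phylo_cov"} object.
#' @param lam lambda in [0, 1.2].
#' @param tol positive-semidefiniteness tolerance, as a fraction of
#'   \code{trace(C)}; the transformed matrix is flagged non-positive-definite
#'   when its smallest eigenvalue is below \code{-tol * trace(C)}.
#' @return \code{cov} with \code{lambda} and \code{C_lambda} set and a
#'   \code{positive_definite} flag.
#' @export
lambda_transform <- function(cov, lam, tol = 1e-8) {
  stopifnot(inherits(cov, "phylo_cov"))
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || lam > 1.2)
    stop("lambda must lie in [0, 1.2]")
  CL <- cov$C * lam
  diag(CL) <- diag(cov$C)
  ev <- eigen(CL, symmetric = TRUE, only.values = TRUE)$values
  cov$lambda <- lam
  cov$C_lambda <- CL
  cov$positive_definite <- min(ev) >= -tol * sum(diag(cov$C))
  cov
}

#' Expand a covariance matrix over duplicated taxa
#'
#' Maps analysis taxa (e.g. species-by-region populations) onto tree tips and
#' expands the covariance accordingly. Two analysis taxa that map to the same
#' tip are treated as sister lineages of zero divergence: each keeps the
#' tip's root-to-tip variance, and their mutual covariance is the tip's full
#' depth, so that a subsequent [lambda_transform()] scales it to
#' \code{lambda * C[tip, tip]} like every other off-diagonal.
#'
#' @param cov a \code{"phylo_cov"} object (base matrix; any existing lambda
#'   transform is re-applied to the expanded matrix).
#' @param mapping named character vector: names are analysis-taxon ids,
#'   values are tip labels present in \code{cov}.
#' @return a \code{"phylo_cov"} over the analysis taxa.
#' @export
expand_duplicated_taxa <- function(cov, mapping) {
  stopifnot(inherits(cov, "phylo_cov"))
  if (is.null(names(mapping)) || any(!nzchar(names(mapping))))
    stop("mapping must be a named character vector (taxon -> tip)")
  unknown <- setdiff(unname(mapping), cov$taxa)
  if (length(unknown))
    stop("mapping references unknown tips: ", paste(unknown, collapse = ", "))
  idx <- match(unname(mapping), cov$taxa)
  C <- cov$C[idx, idx, drop = FALSE]
  # duplicates: off-diagonal between copies of one tip = that tip's depth
  for (i in seq_along(idx)) {
    same <- which(idx == idx[i])
    C[i, same] <- cov$C[idx[i], idx[i]]
  }
  dimnames(C) <- list(names(mapping), names(mapping))
  out <- structure(list(taxa = names(mapping), C = C, lambda = NULL,
                        C_lambda = NULL, positive_definite = TRUE),
                   class = "phylo_cov")
  if (!is.null(cov$lambda)) out <- lambda_transform(out, cov$lambda)
  out
}

#' Write a covariance matrix as CSV
#'
#' @param cov a \code{"phylo_cov"} object.
#' @param file output path.
#' @param which \code{"C"} (base matrix) or \code{"C_lambda"}.
#' @export
write_phylo_cov <- function(cov, file, which = c("C", "C_lambda")) {
  which <- match.arg(which)
  M <- cov[[which]]
  if (is.null(M)) stop(which, " not available")
  write.csv(as.data.frame(M), file, row.names = TRUE)
  invisible(file)
}
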