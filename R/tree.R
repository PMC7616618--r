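#' Parse a Newick tree with validation
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream comparative machinery relies on: unique tip labels, a single
#' root, and non-negative branch lengths. Polytomies and zero-length branches
#' are accepted.
#'
#' @param text Newick string (used if `file` is missing).
#' @param file path to a Newick file; may contain several trees.
#' @return an object of class `phylo`, or `multiPhylo` when `file` holds more
#'   than one tree.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(file)) ape::read.tree(file = file) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) {
    lapply(tr, validate_phylo)
    return(tr)
  }
  validate_phylo(tr)
  tr
}

validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0)
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  invisible(tree)
}

#' Write a tree to Newick
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree) else ape::write.tree(tree, file = file)
}

#' Prune a tree to a set of taxa
#'
#' Produces the induced subtree on `taxa`, merging branch lengths through
#' collapsed unifurcations so root-to-tip path lengths are preserved.
#' Names are matched case-insensitively with spaces and underscores
#' interchangeable. Taxa absent from the tree are reported via a warning.
#'
#' @param tree a `phylo`.
#' @param taxa character vector of tip names to keep.
#' @return the pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, taxa) {
  key <- normalize_species_names(tree$tip.label)
  want <- normalize_species_names(taxa)
  hit <- key %in% want
  missing <- setdiff(want, key)
  if (length(missing) > 0)
    warning(length(missing), " taxa not on the tree: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  if (sum(hit) < 2) stop("fewer than 2 requested taxa are on the tree")
  pr <- ape::keep.tip(tree, tree$tip.label[hit])
  # record the collapsed path from the original root as a root edge, so
  # root-to-tip depths are preserved
  mrca <- ape::getMRCA(tree, tree$tip.label[hit])
  stem <- ape::node.depth.edgelength(tree)[mrca]
  if (!is.null(tree$root.edge)) stem <- stem + tree$root.edge
  if (stem > 0) pr$root.edge <- stem
  pr
}

#' Normalize species names for matching
#'
#' Lower-cases and converts spaces to underscores so trait tables and tree tip
#' labels written with either convention match.
#' @param x character vector.
#' @export
normalize_species_names <- function(x) {
  gsub("[ ]+", "_", tolower(trimws(x)))
}

#' Multiply all branch lengths by a constant
#'
#' Used ahead of transition-rate analyses, where rescaling branch lengths by a
#' small factor (e.g. 0.001) keeps the estimated rates in a numerically
#' comfortable range: a rate q on the scaled tree corresponds to q * factor on
#' the original time scale.
#'
#' @param tree a `phylo`.
#' @param factor positive scalar.
#' @export
scale_branches <- function(tree, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("factor must be a positive scalar")
  tree$edge.length <- tree$edge.length * factor
  tree
}

#' Phylogenetic covariance matrix
#'
#' Brownian-motion covariance: entry (i, j) is the shared root-to-MRCA path
#' length. `lambda` multiplies the off-diagonal entries only (Pagel's lambda
#' rescaling); `lambda = 0` gives the star-phylogeny diagonal matrix. With
#' `include_internal_nodes = TRUE` the matrix covers tips and internal nodes
#' (rows ordered tips first, then nodes in ape numbering), as needed when
#' latent ancestral values enter a model.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param lambda number in \[0, 1\].
#' @param include_internal_nodes logical.
#' @return symmetric covariance matrix with dimnames.
#' @export
phylo_covariance <- function(tree, lambda = 1, include_internal_nodes = FALSE) {
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be in [0, 1]")
  depth <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  if (include_internal_nodes) {
    M <- ape::mrca(tree, full = TRUE)
    ids <- seq_len(ntip + tree$Nnode)
    labs <- c(tree$tip.label, paste0("node", (ntip + 1):(ntip + tree$Nnode)))
  } else {
    M <- ape::mrca(tree, full = FALSE)
    ids <- seq_len(ntip)
    labs <- tree$tip.label
  }
  V <- matrix(depth[M], nrow = length(ids))
  diag(V) <- depth[ids]
  off <- V
  diag(off) <- 0
  V <- diag(diag(V)) + lambda * off
  dimnames(V) <- list(labs, labs)
  V
}

#' Read a posterior sample of trees
#'
#' Reads one or more Newick trees, prunes each to the shared tip universe
#' (optionally intersected with `taxa`), and returns a `multiPhylo` whose
#' members all carry the same tip set.
#'
#' @param file Newick file with one tree per line (or a single tree).
#' @param taxa optional taxa to restrict to.
#' @export
read_tree_sample <- function(file, taxa = NULL) {
  trs <- ape::read.tree(file = file)
  if (inherits(trs, "phylo")) trs <- c(trs)
  lapply(trs, validate_phylo)
  common <- Reduce(intersect, lapply(trs, function(t) t$tip.label))
  if (!is.null(taxa)) {
    keep <- normalize_species_names(common) %in% normalize_species_names(taxa)
    common <- common[keep]
  }
  if (length(common) < 2) stop("fewer than 2 shared taxa across the tree sample")
  out <- lapply(trs, ape::keep.tip, tip = common)
  class(out) <- "multiPhylo"
  out
}
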