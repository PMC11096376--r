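# Phylogenetic variance-covariance matrices from Newick trees.
#
# Under Brownian-motion evolution the expected covariance between the
# trait values of two species equals the branch length they share from
# the root to their most recent common ancestor. The correlation form
# (unit diagonal) is what enters the mixed models as the phylogenetic
# random-effect structure.

#' Read and validate a Newick tree
#'
#' Parses a rooted Newick tree with branch lengths and validates it for
#' use as the phylogenetic input: unique tip labels, branch lengths
#' present and non-negative, rooted.
#'
#' @param path path to a Newick file, or a Newick string ending in ";".
#' @param labels normalization for tip labels: `"underscore"` converts
#'   spaces to underscores, `"space"` the reverse, `"none"` leaves them.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path, labels = c("none", "underscore", "space")) {
  labels <- match.arg(labels)
  looks_like_newick <- grepl("[();]", path[1])
  tree <- if (looks_like_newick && !file.exists(path[1])) {
    tryCatch(suppressWarnings(ape::read.tree(text = path)),
             error = function(e) NULL)
  } else {
    if (!file.exists(path)) stop("tree file not found: ", path)
    tryCatch(suppressWarnings(ape::read.tree(path)),
             error = function(e) NULL)
  }
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("could not parse Newick input: ", path[1])
  }
  if (labels == "underscore") tree$tip.label <- gsub(" ", "_", tree$tip.label)
  if (labels == "space") tree$tip.label <- gsub("_", " ", tree$tip.label)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (any(tree$tip.label == "")) stop("tree contains unlabelled tips")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("branch lengths must all be present and >= 0")
  }
  # note: a basal polytomy (star tree) is accepted; the parsed edge
  # structure always carries a single root node, which is what the
  # root-to-tip covariance needs
  invisible(tree)
}

#' Phylogenetic variance-covariance from a tree
#'
#' `C[i, j]` is the root-to-tip branch length shared by tips i and j
#' (the depth of their most recent common ancestor); the diagonal holds
#' full root-to-tip distances. `C_corr` is the correlation form
#' `D^{-1/2} C D^{-1/2}`, which the mixed models use so that the
#' phylogenetic variance component stays on the same scale as the
#' i.i.d. components.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return an object of class `phylo_cov`: list with `species`, `C`,
#'   `C_corr`.
#' @export
vcv_from_tree <- function(tree) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)  # distance from root, all nodes
  if (n == 1) {
    C <- matrix(sum(tree$edge.length), 1, 1)
  } else {
    anc <- ape::mrca(tree)                    # n x n matrix of MRCA node ids
    C <- matrix(depths[anc], n, n)
  }
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  diag(C) <- depths[seq_len(n)]
  # a root edge is ancestral branch shared by every tip (kept by pruning)
  if (!is.null(tree$root.edge) && is.finite(tree$root.edge)) {
    C <- C + tree$root.edge
  }
  d <- diag(C)
  if (any(d <= 0)) stop("zero root-to-tip distance; cannot form correlation")
  if (max(d) - min(d) > 1e-8 * max(d)) {
    warning("tree is not ultrametric; correlation scaling applied anyway")
  }
  C_corr <- C / sqrt(outer(d, d))
  diag(C_corr) <- 1
  structure(list(species = tree$tip.label, C = C, C_corr = C_corr),
            class = "phylo_cov")
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat("Phylogenetic covariance over", length(x$species), "species\n")
  cat("  mean off-diagonal correlation:",
      signif(mean(x$C_corr[upper.tri(x$C_corr)]), 3), "\n")
  invisible(x)
}

#' Prune a tree to a species set
#'
#' Returns the induced subtree on `species`, with degree-2 internal
#' nodes collapsed and their branch lengths summed. The path from the
#' original root down to the retained species' common ancestor is kept
#' as the pruned tree's root edge, so that the pruned tree's covariance
#' matrix equals the corresponding submatrix of the full tree's
#' exactly.
#'
#' @param tree a `phylo`.
#' @param species character vector of tip labels to keep.
#' @return a `phylo`; pruning to a single species returns a degenerate
#'   one-tip tree with a warning.
#' @export
prune_to_species <- function(tree, species) {
  species <- unique(species)
  missing <- setdiff(species, tree$tip.label)
  if (length(missing)) {
    stop("species missing from tree: ", paste(missing, collapse = ", "))
  }
  base <- if (!is.null(tree$root.edge) && is.finite(tree$root.edge)) {
    tree$root.edge
  } else {
    0
  }
  depths <- ape::node.depth.edgelength(tree)
  if (length(species) == 1) {
    warning("pruning to a single tip: degenerate one-branch tree")
    tip <- match(species, tree$tip.label)
    out <- list(edge = matrix(c(2L, 1L), 1, 2),
                edge.length = depths[tip] + base,
                tip.label = species, Nnode = 1L)
    class(out) <- "phylo"
    attr(out, "order") <- "cladewise"
    return(out)
  }
  out <- ape::keep.tip(tree, species)
  mrca_depth <- if (length(species) == length(tree$tip.label)) 0
                else depths[ape::getMRCA(tree, species)]
  out$root.edge <- base + mrca_depth
  out
}
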