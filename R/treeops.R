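# Path-based tree metrics. All distances are computed on the unrooted
# topology; patristic distance sums branch lengths, edge count counts
# edges, so both are invariant to where a tree tool happened to root.

.asPhylo <- function(tree) {
  tr <- if (is(tree, "LabeledTree")) tree@tree else tree
  if (ape::is.rooted(tr) && length(tr$tip.label) >= 3L)
    tr <- ape::unroot(tr)
  tr
}

#' All-pairs leaf distances
#'
#' Patristic (branch-length) and topological (edge-count) distances between
#' every pair of leaves, as two symmetric matrices.
#'
#' @param tree a [LabeledTree-class] or `ape::phylo`.
#' @return list with elements `patristic` (numeric matrix) and `edges`
#'   (integer-valued matrix), both with leaf labels as dimnames.
#' @export
leafDistances <- function(tree) {
  tr <- .asPhylo(tree)
  pat <- ape::cophenetic.phylo(tr)
  trE <- tr
  trE$edge.length <- rep(1, nrow(trE$edge))
  edg <- ape::cophenetic.phylo(trE)
  ord <- tr$tip.label
  list(patristic = pat[ord, ord, drop = FALSE],
       edges = edg[ord, ord, drop = FALSE])
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths on the unique path between leaves `a` and `b`.
#'
#' @param tree a [LabeledTree-class] or `ape::phylo`.
#' @param a,b leaf labels.
#' @return non-negative numeric; 0 when `a == b`.
#' @export
patristicDistance <- function(tree, a, b) {
  tr <- .asPhylo(tree)
  .checkLeaf(tr, a); .checkLeaf(tr, b)
  if (a == b) return(0)
  d <- ape::cophenetic.phylo(tr)
  unname(d[a, b])
}

#' Edge count between two leaves
#'
#' Number of edges on the path between leaves `a` and `b` in the unrooted
#' tree. Zero-length branches still count.
#'
#' @inheritParams patristicDistance
#' @return non-negative integer; 0 when `a == b`, >= 2 for distinct leaves
#'   (leaf - internal node - leaf at minimum, except 2-leaf trees).
#' @export
edgeCount <- function(tree, a, b) {
  tr <- .asPhylo(tree)
  .checkLeaf(tr, a); .checkLeaf(tr, b)
  if (a == b) return(0L)
  trE <- tr
  trE$edge.length <- rep(1, nrow(trE$edge))
  as.integer(round(ape::cophenetic.phylo(trE)[a, b]))
}

.checkLeaf <- function(tr, x) {
  if (!x %in% tr$tip.label) stop("unknown leaf: ", x)
  invisible(TRUE)
}

#' Mean nearest taxon distance
#'
#' Mean, over all leaves, of the patristic distance to each leaf's nearest
#' other leaf. Used to scale the outlier cutoff in classification and the
#' grouping cutoff in paralog collapsing.
#'
#' @param tree a [LabeledTree-class] or `ape::phylo` with at least 2 leaves.
#' @return non-negative numeric.
#' @export
meanNearestTaxonDistance <- function(tree) {
  tr <- .asPhylo(tree)
  if (length(tr$tip.label) < 2L) stop("MNTD needs at least 2 leaves")
  d <- ape::cophenetic.phylo(tr)
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}
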