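#' @import methods
#' @importFrom stats runif setNames
#' @importFrom utils read.table write.table head tail
NULL

setOldClass("phylo")

.LEAF_ROLES <- c("ingroup_bait", "outgroup_bait", "candidate", "reference")

#' Phylogeny with per-leaf role tags
#'
#' A `LabeledTree` couples an [ape::phylo] topology (with branch lengths)
#' with a role tag for every leaf. Roles distinguish ingroup baits (known
#' bHLHs), outgroup baits (bHLH-similar non-bHLHs), candidates under
#' classification, and reference landmarks. All tree metrics in this
#' package treat the topology as unrooted, so rooting artifacts introduced
#' by tree-building tools do not affect distances.
#'
#' @slot tree an `ape::phylo` object; branch lengths must be present and
#'   non-negative (zero-length branches are allowed).
#' @slot roles named character vector mapping every tip label to one of
#'   `"ingroup_bait"`, `"outgroup_bait"`, `"candidate"`, `"reference"`.
#'
#' @seealso [labeledTree()], [patristicDistance()], [classifyLeaf()]
#' @export
setClass("LabeledTree",
  representation(tree = "phylo", roles = "character"))

setValidity("LabeledTree", function(object) {
  msgs <- character()
  tr <- object@tree
  tips <- tr$tip.label
  if (anyDuplicated(tips))
    msgs <- c(msgs, "duplicate leaf labels")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    msgs <- c(msgs, "tree must have complete branch lengths")
  else if (any(tr$edge.length < -1e-12))
    msgs <- c(msgs, "negative branch lengths")
  if (!setequal(names(object@roles), tips))
    msgs <- c(msgs, "roles must be named by the tip labels, one per leaf")
  bad <- setdiff(unique(object@roles), .LEAF_ROLES)
  if (length(bad))
    msgs <- c(msgs, paste0("unknown roles: ", paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabeledTree
#'
#' @param tree an `ape::phylo`, or a Newick string / file path parsed with
#'   [ape::read.tree()].
#' @param roles named character vector of leaf roles (see [LabeledTree-class]),
#'   named by tip label. Every tip must be covered.
#' @return a [LabeledTree-class] object. The topology is stored unrooted.
#' @examples
#' tr <- labeledTree("((C1:1,B1:1):1,(B2:1,O1:2):1);",
#'   c(C1 = "candidate", B1 = "ingroup_bait",
#'     B2 = "ingroup_bait", O1 = "outgroup_bait"))
#' leafRoles(tr)
#' @export
labeledTree <- function(tree, roles) {
  if (is.character(tree) && length(tree) == 1L) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  # a Newick edge without a stated length (often internal stems) counts 0
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (ape::is.rooted(tree) && length(tree$tip.label) >= 3L)
    tree <- ape::unroot(tree)
  missing <- setdiff(tree$tip.label, names(roles))
  if (length(missing))
    stop("no role supplied for leaves: ", paste(missing, collapse = ", "))
  roles <- roles[tree$tip.label]
  new("LabeledTree", tree = tree, roles = roles)
}

#' @describeIn LabeledTree-class underlying `ape::phylo`
#' @param x a `LabeledTree`
#' @export
treePhylo <- function(x) x@tree

#' @describeIn LabeledTree-class named character vector of leaf roles
#' @export
leafRoles <- function(x) x@roles

#' @describeIn LabeledTree-class tip labels with role `ingroup_bait` or
#'   `outgroup_bait`
#' @export
baitLeaves <- function(x) names(x@roles)[x@roles %in% c("ingroup_bait", "outgroup_bait")]

#' @describeIn LabeledTree-class tip labels with role `candidate`
#' @export
candidateLeaves <- function(x) names(x@roles)[x@roles == "candidate"]

setMethod("show", "LabeledTree", function(object) {
  n <- table(factor(object@roles, levels = .LEAF_ROLES))
  cat("LabeledTree with", length(object@roles), "leaves\n")
  cat("  ingroup baits:", n[["ingroup_bait"]],
      " outgroup baits:", n[["outgroup_bait"]],
      " candidates:", n[["candidate"]],
      " references:", n[["reference"]], "\n")
})

#' Classification parameters
#'
#' Tunables of the ingroup/outgroup classification of candidate leaves by
#' their nearest bait neighbours in the tree.
#'
#' @slot nNeighbours number of bait leaves considered per candidate
#'   (default 3).
#' @slot minScore minimum ingroup fraction; a candidate is ingroup only if
#'   its score is strictly greater than this (default 0.5).
#' @slot outlierFactor leaves farther than `outlierFactor` times the tree's
#'   mean nearest taxon distance are dropped from the neighbourhood before
#'   selection (default 5).
#' @slot minBaitsInSelection minimum total number of baits that must remain
#'   in the selection for a candidate to be classifiable as ingroup
#'   (default 1).
#' @slot requireDomain if `TRUE`, a candidate without a detected bHLH
#'   domain is labelled outgroup regardless of its score (default `FALSE`).
#' @slot parallelThreshold candidate count above which the classification
#'   tree is built per bin rather than once (default 600).
#' @slot binSize candidates per bin when binning is triggered (default 500).
#' @export
setClass("ClassifyParams",
  representation(nNeighbours = "integer", minScore = "numeric",
    outlierFactor = "numeric", minBaitsInSelection = "integer",
    requireDomain = "logical", parallelThreshold = "integer",
    binSize = "integer"))

setValidity("ClassifyParams", function(object) {
  msgs <- character()
  if (object@nNeighbours < 1L) msgs <- c(msgs, "nNeighbours must be >= 1")
  if (object@minScore < 0 || object@minScore > 1)
    msgs <- c(msgs, "minScore must be in [0, 1]")
  if (object@outlierFactor <= 0) msgs <- c(msgs, "outlierFactor must be > 0")
  if (object@minBaitsInSelection < 0L)
    msgs <- c(msgs, "minBaitsInSelection must be >= 0")
  if (object@binSize < 1L) msgs <- c(msgs, "binSize must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ClassifyParams-class
#' @param nNeighbours,minScore,outlierFactor,minBaitsInSelection,requireDomain,parallelThreshold,binSize
#'   see the corresponding slots.
#' @return a `ClassifyParams` object.
#' @export
classifyParams <- function(nNeighbours = 3L, minScore = 0.5,
                           outlierFactor = 5, minBaitsInSelection = 1L,
                           requireDomain = FALSE, parallelThreshold = 600L,
                           binSize = 500L) {
  new("ClassifyParams", nNeighbours = as.integer(nNeighbours),
      minScore = as.numeric(minScore), outlierFactor = as.numeric(outlierFactor),
      minBaitsInSelection = as.integer(minBaitsInSelection),
      requireDomain = isTRUE(requireDomain),
      parallelThreshold = as.integer(parallelThreshold),
      binSize = as.integer(binSize))
}

setMethod("show", "ClassifyParams", function(object) {
  cat("ClassifyParams:",
      sprintf("nNeighbours=%d minScore=%g outlierFactor=%g minBaits=%d requireDomain=%s parallelThreshold=%d binSize=%d\n",
              object@nNeighbours, object@minScore, object@outlierFactor,
              object@minBaitsInSelection, object@requireDomain,
              object@parallelThreshold, object@binSize))
})
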