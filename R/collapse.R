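# Collapsing clades of near-identical candidates (transcript isoforms or
# close paralogs) into one representative each, for de novo transcriptome
# assemblies where one gene is typically present as many isoforms.

#' Group candidate leaves into paralog groups
#'
#' Candidate leaves are visited as seeds in lexicographic id order. For an
#' ungrouped seed, the other leaves are walked in ascending edge-distance
#' order (ties: patristic, then id); candidate leaves with a patristic
#' distance to the seed strictly below `cutoffFactor` times the tree's mean
#' nearest taxon distance join the group, and the walk stops at the first
#' bait leaf, so candidates beyond the nearest bait are never considered
#' for that group. Grouped members neither seed nor join another group, so
#' the groups partition the candidate set. The member with the longest
#' (unaligned) sequence represents the group, ties broken by id.
#'
#' @param tree the final [LabeledTree-class] (candidate + bait leaves).
#' @param sequences named `AAStringSet` covering every candidate leaf (for
#'   representative length lookup).
#' @param cutoffFactor multiplier on the mean nearest taxon distance
#'   (default 1).
#' @return data.frame, one row per group: `group` (integer id), `seed`,
#'   `representative`, `members` (comma-separated), `n_members`.
#' @export
collapseParalogs <- function(tree, sequences, cutoffFactor = 1) {
  stopifnot(is(tree, "LabeledTree"), cutoffFactor > 0)
  roles <- leafRoles(tree)
  cands <- sort(candidateLeaves(tree))
  if (!length(cands)) {
    return(data.frame(group = integer(), seed = character(),
                      representative = character(), members = character(),
                      n_members = integer(), stringsAsFactors = FALSE))
  }
  noSeq <- setdiff(cands, names(sequences))
  if (length(noSeq))
    stop("no sequence record for candidates: ", paste(noSeq, collapse = ", "))
  mntd <- meanNearestTaxonDistance(tree)
  cutoff <- cutoffFactor * mntd
  dists <- leafDistances(tree)
  grouped <- character()
  rows <- list()
  g <- 0L
  for (seed in cands) {
    if (seed %in% grouped) next
    others <- setdiff(names(roles), seed)
    ord <- others[order(dists$edges[seed, others],
                        dists$patristic[seed, others], others,
                        method = "radix")]
    members <- seed
    for (leaf in ord) {
      if (roles[[leaf]] != "candidate") break  # stop at the first bait
      if (leaf %in% grouped) next
      if (dists$patristic[seed, leaf] < cutoff) members <- c(members, leaf)
    }
    grouped <- c(grouped, members)
    lens <- Biostrings::width(sequences[members])
    rep <- members[order(-lens, members, method = "radix")][1L]
    g <- g + 1L
    rows[[g]] <- data.frame(group = g, seed = seed, representative = rep,
                            members = paste(sort(members), collapse = ","),
                            n_members = length(members),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build trees of group representatives
#'
#' Aligns the representatives with the bait (or landmark) sequences, trims,
#' and builds a tree. When a reference table is supplied, reference leaves
#' are relabelled `id|alt_name|subfamily` so subfamily context is visible
#' in the Newick output.
#'
#' @param representatives,anchors named `AAStringSet`s (anchors = baits or
#'   landmark references).
#' @param referenceTable optional data.frame (`id`, `alt_name`,
#'   `subfamily`) used for the decorated labels.
#' @param alignTool,treeTool,seed see [alignSequences()] / [buildTree()].
#' @param anchorRole role given to anchor leaves (default
#'   `"ingroup_bait"`; use `"reference"` for landmark trees).
#' @return a [LabeledTree-class]; decorated labels are applied after the
#'   tree is built so tree tools only ever see clean ids.
#' @export
representativeTree <- function(representatives, anchors,
                               referenceTable = NULL, alignTool = "mafft",
                               treeTool = "fasttree", seed = 1L,
                               anchorRole = "ingroup_bait") {
  all <- c(representatives, anchors)
  aln <- alignSequences(all, tool = alignTool)
  trimmed <- trimAlignment(aln)$alignment
  tr <- buildTree(trimmed, tool = treeTool, seed = seed)
  roles <- c(setNames(rep("candidate", length(representatives)),
                      names(representatives)),
             setNames(rep(anchorRole, length(anchors)), names(anchors)))
  if (!is.null(referenceTable)) {
    i <- match(tr$tip.label, referenceTable$id)
    deco <- ifelse(is.na(i), tr$tip.label,
                   paste(tr$tip.label, referenceTable$alt_name[i],
                         referenceTable$subfamily[i], sep = "|"))
    names(roles)[match(tr$tip.label, names(roles))] <- deco
    tr$tip.label <- deco
  }
  labeledTree(tr, roles)
}
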