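# Independent brute-force oracles used to cross-check the package's tree
# metrics, classification, trimming and collapsing. These deliberately
# take a different route than the implementation: shortest paths on the
# tree graph via igraph instead of cophenetic matrices, explicit loops
# instead of vectorised column math.

# all-pairs leaf distances by weighted/unweighted shortest paths on the
# tree's edge graph
oracleDistances <- function(phy) {
  if (inherits(phy, "LabeledTree")) phy <- treePhylo(phy)
  if (ape::is.rooted(phy) && length(phy$tip.label) >= 3L)
    phy <- ape::unroot(phy)
  g <- igraph::graph_from_edgelist(cbind(phy$edge[, 1], phy$edge[, 2]),
                                   directed = FALSE)
  ntip <- length(phy$tip.label)
  pat <- igraph::distances(g, weights = phy$edge.length)[seq_len(ntip),
                                                         seq_len(ntip)]
  edg <- igraph::distances(g, weights = rep(1, nrow(phy$edge)))[seq_len(ntip),
                                                                seq_len(ntip)]
  dimnames(pat) <- dimnames(edg) <- list(phy$tip.label, phy$tip.label)
  list(patristic = pat, edges = edg)
}

oracleMntd <- function(phy) {
  d <- oracleDistances(phy)$patristic
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# brute-force neighbourhood classification of one candidate leaf
oracleClassifyLeaf <- function(ltree, candidate, nNeighbours = 3L,
                               minScore = 0.5, outlierFactor = 5,
                               minBaits = 1L) {
  roles <- leafRoles(ltree)
  d <- oracleDistances(ltree)
  mntd <- oracleMntd(ltree)
  baits <- names(roles)[roles %in% c("ingroup_bait", "outgroup_bait")]
  baits <- setdiff(baits, candidate)
  keep <- baits[d$patristic[candidate, baits] <= outlierFactor * mntd]
  ord <- keep[order(d$edges[candidate, keep], d$patristic[candidate, keep],
                    keep, method = "radix")]
  sel <- head(ord, nNeighbours)
  nIn <- sum(roles[sel] == "ingroup_bait")
  nOut <- sum(roles[sel] == "outgroup_bait")
  score <- if (nIn + nOut == 0) 0 else nIn / (nIn + nOut)
  label <- if (nIn + nOut > 0 && score > minScore && nIn + nOut >= minBaits)
    "ingroup" else "outgroup"
  list(n_in = nIn, n_out = nOut, score = score, label = label,
       selected = sel)
}

# per-column occupancy recount with explicit loops
oracleTrim <- function(chrRows, minOccupancy = 0.10) {
  m <- do.call(rbind, strsplit(chrRows, ""))
  kept <- integer()
  for (j in seq_len(ncol(m))) {
    occ <- sum(m[, j] != "-" & m[, j] != ".") / nrow(m)
    if (occ >= minOccupancy) kept <- c(kept, j)
  }
  kept
}

# brute-force paralog grouping with explicit distance matrices and the
# same walk rules (sorted seeds, edge-ordered walk, stop at first bait,
# strict patristic cutoff, exclusion of grouped members)
oracleCollapse <- function(ltree, widths, cutoffFactor = 1) {
  roles <- leafRoles(ltree)
  d <- oracleDistances(ltree)
  cutoff <- cutoffFactor * oracleMntd(ltree)
  cands <- sort(names(roles)[roles == "candidate"])
  grouped <- character()
  groups <- list()
  for (seed in cands) {
    if (seed %in% grouped) next
    others <- setdiff(names(roles), seed)
    ord <- others[order(d$edges[seed, others], d$patristic[seed, others],
                        others, method = "radix")]
    members <- seed
    for (leaf in ord) {
      if (roles[[leaf]] != "candidate") break
      if (leaf %in% grouped) next
      if (d$patristic[seed, leaf] < cutoff) members <- c(members, leaf)
    }
    grouped <- c(grouped, members)
    rep <- members[order(-widths[members], members, method = "radix")][1]
    groups[[seed]] <- list(members = sort(members), representative = rep)
  }
  groups
}

# random alignment-like character rows (no biological meaning)
randomAlignmentRows <- function(nrow, ncol, gapProb = 0.5) {
  rows <- vapply(seq_len(nrow), function(i) {
    ch <- sample(c("-", "A", "R", "K", "X"), ncol, replace = TRUE,
                 prob = c(gapProb, rep((1 - gapProb) / 4, 4)))
    paste(ch, collapse = "")
  }, character(1))
  names(rows) <- sprintf("row%02d", seq_len(nrow))
  rows
}
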