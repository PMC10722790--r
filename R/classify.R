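# Ingroup/outgroup classification of candidate leaves from the composition
# of their nearest bait neighbours in a phylogenetic tree. Only bait leaves
# vote; candidate leaves are never counted in a neighbourhood. Run twice
# (the second pass on a cleaner tree) to drop candidates accepted on the
# strength of a noisy first alignment.

#' Classify one candidate leaf
#'
#' The candidate's neighbourhood is the set of bait leaves sorted by
#' ascending edge count, with ties broken by ascending patristic distance
#' and then lexicographic id (so results are independent of leaf input
#' order). Bait leaves farther than `outlierFactor` times the tree's mean
#' nearest taxon distance are removed before selection; the first
#' `nNeighbours` survivors vote. The score is the ingroup fraction
#' `n_in / (n_in + n_out)`; the candidate is labelled ingroup iff the score
#' is strictly greater than `minScore`, at least `minBaitsInSelection`
#' baits voted, and (when `requireDomain`) its bHLH domain was detected.
#'
#' @param tree a [LabeledTree-class] containing the candidate plus ingroup
#'   and outgroup bait leaves.
#' @param candidate a candidate leaf label.
#' @param params a [classifyParams()] object.
#' @param mntd mean nearest taxon distance of the tree; computed when `NULL`.
#' @param domainPresent was the bHLH domain detected in this candidate?
#' @param dists optional precomputed [leafDistances()] of `tree` (reuse when
#'   classifying many leaves of one tree).
#' @return one-row data.frame: `candidate`, `n_in`, `n_out`, `score`,
#'   `label`, `domain_present`, `flag` (`""` or `"no_baits"`), and
#'   comma-separated `selected_neighbours` and `excluded_outliers`.
#' @examples
#' tr <- labeledTree("((C1:0.1,(I1:0.1,I2:0.1):0.1):0.1,(O1:0.1,(I3:1,O2:0.1):0.1):0.1);",
#'   c(C1 = "candidate", I1 = "ingroup_bait", I2 = "ingroup_bait",
#'     I3 = "ingroup_bait", O1 = "outgroup_bait", O2 = "outgroup_bait"))
#' classifyLeaf(tr, "C1")
#' @export
classifyLeaf <- function(tree, candidate, params = classifyParams(),
                         mntd = NULL, domainPresent = TRUE, dists = NULL) {
  stopifnot(is(tree, "LabeledTree"))
  roles <- leafRoles(tree)
  if (!candidate %in% names(roles)) stop("unknown leaf: ", candidate)
  if (is.null(mntd)) mntd <- meanNearestTaxonDistance(tree)
  if (is.null(dists)) dists <- leafDistances(tree)
  baits <- baitLeaves(tree)
  baits <- setdiff(baits, candidate)
  pat <- dists$patristic[candidate, baits]
  edg <- dists$edges[candidate, baits]
  cutoff <- params@outlierFactor * mntd
  outliers <- baits[pat > cutoff]
  kept <- setdiff(baits, outliers)
  ord <- kept[order(edg[kept], pat[kept], kept, method = "radix")]
  sel <- utils::head(ord, params@nNeighbours)
  nIn <- sum(roles[sel] == "ingroup_bait")
  nOut <- sum(roles[sel] == "outgroup_bait")
  total <- nIn + nOut
  flag <- ""
  if (total == 0L) {
    score <- 0
    flag <- "no_baits"
  } else {
    score <- nIn / total
  }
  label <- if (score > params@minScore && total >= params@minBaitsInSelection &&
               (domainPresent || !params@requireDomain) && flag == "")
    "ingroup" else "outgroup"
  data.frame(candidate = candidate, n_in = nIn, n_out = nOut, score = score,
             label = label, domain_present = domainPresent, flag = flag,
             selected_neighbours = paste(sel, collapse = ","),
             excluded_outliers = paste(sort(outliers), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Classify all candidate leaves of one LabeledTree
#'
#' @param tree a [LabeledTree-class].
#' @param params a [classifyParams()] object.
#' @param domainPresent named logical vector over candidates (default: all
#'   `TRUE`).
#' @return data.frame, one [classifyLeaf()] row per candidate leaf.
#' @export
classifyTree <- function(tree, params = classifyParams(),
                         domainPresent = NULL) {
  cands <- candidateLeaves(tree)
  if (!length(cands)) return(NULL)
  mntd <- meanNearestTaxonDistance(tree)
  dists <- leafDistances(tree)
  if (is.null(domainPresent))
    domainPresent <- setNames(rep(TRUE, length(cands)), cands)
  do.call(rbind, lapply(cands, function(cd)
    classifyLeaf(tree, cd, params, mntd = mntd,
                 domainPresent = isTRUE(domainPresent[[cd]]), dists = dists)))
}

#' One classification pass: align, trim, tree, classify
#'
#' Aligns candidates together with the full bait and outgroup collections,
#' trims columns below 10% occupancy, builds a tree, screens candidates for
#' the family domain HMM (when supplied), and classifies every candidate
#' leaf. When more than `parallelThreshold` candidates are supplied they
#' are partitioned, in input order, into bins of `binSize`; each bin is
#' aligned and treed with the complete bait + outgroup set so every bin's
#' tree is anchored, and the per-bin results are concatenated.
#'
#' @param candidates,baits,outgroup named `AAStringSet`s.
#' @param params a [classifyParams()] object.
#' @param domainHmm optional path to the family profile HMM (required when
#'   `params@requireDomain`).
#' @param alignTool,treeTool passed to [alignSequences()] / [buildTree()].
#' @param seed integer seed forwarded to the tree tool.
#' @return list: `ingroup` and `outgroup` id vectors, `results` data.frame
#'   (with a `bin` column), and `trees`, one [LabeledTree-class] per bin.
#' @export
classifyPass <- function(candidates, baits, outgroup,
                         params = classifyParams(), domainHmm = NULL,
                         alignTool = "mafft", treeTool = "fasttree",
                         seed = 1L) {
  if (!length(candidates)) stop("candidate set is empty")
  domPresent <- if (!is.null(domainHmm)) {
    hits <- .hmmsearch(domainHmm, candidates)
    setNames(names(candidates) %in% hits$target, names(candidates))
  } else {
    setNames(rep(TRUE, length(candidates)), names(candidates))
  }
  idx <- seq_along(candidates)
  bins <- if (length(candidates) > params@parallelThreshold) {
    split(idx, ceiling(idx / params@binSize))
  } else {
    list(`1` = idx)
  }
  results <- list()
  trees <- list()
  roleAnchors <- c(setNames(rep("ingroup_bait", length(baits)), names(baits)),
                   setNames(rep("outgroup_bait", length(outgroup)), names(outgroup)))
  for (b in names(bins)) {
    binCand <- candidates[bins[[b]]]
    all <- c(binCand, baits, outgroup)
    tr <- tryCatch({
      aln <- alignSequences(all, tool = alignTool)
      trimmed <- trimAlignment(aln)$alignment
      buildTree(trimmed, tool = treeTool, seed = seed)
    }, error = function(e) stop("classification failed in bin ", b, ": ",
                                conditionMessage(e)))
    roles <- c(setNames(rep("candidate", length(binCand)), names(binCand)),
               roleAnchors)
    ltree <- labeledTree(tr, roles)
    res <- classifyTree(ltree, params, domainPresent = domPresent)
    res$bin <- as.integer(b)
    results[[b]] <- res
    trees[[b]] <- ltree
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL
  list(ingroup = results$candidate[results$label == "ingroup"],
       outgroup = results$candidate[results$label == "outgroup"],
       results = results, trees = trees)
}

#' Two-pass classification
#'
#' Runs [classifyPass()] on the initial candidates, then a second pass on
#' the first pass's ingroup only; a cleaner alignment in the second pass
#' filters candidates that were falsely accepted. The final set is the
#' second pass's ingroup, so `final` is always a subset of `pass1 ingroup`,
#' itself a subset of the initial candidates.
#'
#' @inheritParams classifyPass
#' @return list: `final` (character ids), `pass1`, `pass2` (each a
#'   [classifyPass()] result; `pass2` is `NULL` when pass 1 kept nothing).
#' @export
twoPassClassify <- function(candidates, baits, outgroup,
                            params = classifyParams(), domainHmm = NULL,
                            alignTool = "mafft", treeTool = "fasttree",
                            seed = 1L) {
  p1 <- classifyPass(candidates, baits, outgroup, params, domainHmm,
                     alignTool, treeTool, seed)
  if (!length(p1$ingroup)) {
    warning("first classification pass retained no candidates")
    return(list(final = character(), pass1 = p1, pass2 = NULL))
  }
  p2 <- classifyPass(candidates[p1$ingroup], baits, outgroup, params,
                     domainHmm, alignTool, treeTool, seed)
  list(final = p2$ingroup, pass1 = p1, pass2 = p2)
}
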