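# Ortholog assignment and annotation transfer. The bait with the minimum
# edge distance to a candidate in the final tree is its ortholog; ties are
# broken by minimum patristic distance, then lexicographic bait id, so the
# assignment is a deterministic total function on candidates.

#' Assign an ortholog bait to every candidate
#'
#' @param tree the final [LabeledTree-class] (candidate + bait leaves).
#' @param candidates candidate leaf labels (default: all candidate leaves).
#' @return data.frame with one row per candidate: `candidate`, `bait`,
#'   `edge_distance`, `patristic_distance`. The reverse index (candidates
#'   per bait) is attached as attribute `"byBait"`, a named list that
#'   partitions the candidates.
#' @export
assignOrthologs <- function(tree, candidates = candidateLeaves(tree)) {
  stopifnot(is(tree, "LabeledTree"))
  baits <- baitLeaves(tree)
  if (!length(baits)) stop("tree contains no bait leaves")
  missing <- setdiff(candidates, names(leafRoles(tree)))
  if (length(missing))
    stop("candidates absent from tree: ", paste(missing, collapse = ", "))
  dists <- leafDistances(tree)
  rows <- lapply(candidates, function(cd) {
    edg <- dists$edges[cd, baits]
    pat <- dists$patristic[cd, baits]
    best <- baits[order(edg, pat, baits, method = "radix")][1L]
    data.frame(candidate = cd, bait = best,
               edge_distance = as.integer(round(dists$edges[cd, best])),
               patristic_distance = unname(dists$patristic[cd, best]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "byBait") <- split(out$candidate, out$bait)
  out
}

#' Transfer functional annotation from the reference table
#'
#' Candidates whose ortholog bait is a reference entry receive its
#' functional description, alternative name and subfamily; candidates
#' assigned to a non-reference bait keep the bait id with empty annotation
#' fields.
#'
#' @param assignments data.frame from [assignOrthologs()].
#' @param referenceTable data.frame from [readReferenceTable()] (columns
#'   `id`, `description`, `alt_name`, `subfamily`), or `NULL`.
#' @return the assignment table extended with `description`, `alt_name`,
#'   `subfamily` character columns (empty string when not a reference).
#' @export
annotateCandidates <- function(assignments, referenceTable = NULL) {
  out <- assignments
  if (is.null(out) || !nrow(out)) {
    out$description <- character(0); out$alt_name <- character(0)
    out$subfamily <- character(0)
    return(out)
  }
  i <- if (is.null(referenceTable)) rep(NA_integer_, nrow(out))
       else match(out$bait, referenceTable$id)
  pick <- function(col) ifelse(is.na(i), "", referenceTable[[col]][i])
  out$description <- pick("description")
  out$alt_name <- pick("alt_name")
  out$subfamily <- pick("subfamily")
  out
}

#' Assign subfamilies from a landmark tree
#'
#' Each representative inherits the subfamily of its nearest reference leaf
#' (minimum edge distance; ties by patristic distance then id — the same
#' metric as ortholog assignment). An approximation of clade membership
#' that is exact when subfamilies are monophyletic around the
#' representative.
#'
#' @param tree a [LabeledTree-class] whose reference leaves carry role
#'   `"reference"` (or `"ingroup_bait"` when baits double as references).
#' @param representatives leaf labels to assign.
#' @param referenceTable data.frame with `id` and `subfamily` columns.
#' @return data.frame: `representative`, `reference`, `subfamily`.
#' @export
assignSubfamily <- function(tree, representatives, referenceTable) {
  stopifnot(is(tree, "LabeledTree"))
  roles <- leafRoles(tree)
  refLeaves <- intersect(names(roles)[roles %in% c("reference", "ingroup_bait")],
                         referenceTable$id)
  if (!length(refLeaves)) stop("tree contains no reference leaves")
  dists <- leafDistances(tree)
  rows <- lapply(representatives, function(rp) {
    edg <- dists$edges[rp, refLeaves]
    pat <- dists$patristic[rp, refLeaves]
    best <- refLeaves[order(edg, pat, refLeaves, method = "radix")][1L]
    data.frame(representative = rp, reference = best,
               subfamily = referenceTable$subfamily[match(best, referenceTable$id)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
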