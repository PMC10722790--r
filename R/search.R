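#' Search thresholds for BLAST candidate filtering
#'
#' Hits must reach all three minima (inclusive) to survive: bit score,
#' percent identity ("similarity"), and alignment length. Defaults follow
#' the published cutoffs of 60 bits and 40% similarity; the alignment
#' length default of 80 aa spans the ~60-aa bHLH domain plus flanks and is
#' freely configurable.
#'
#' @param minBitScore minimum bit score (default 60).
#' @param minSimilarity minimum percent identity, 0-100 (default 40).
#' @param minAlignLength minimum alignment length in residues (default 80).
#' @return list of class `SearchThresholds`.
#' @export
searchThresholds <- function(minBitScore = 60, minSimilarity = 40,
                             minAlignLength = 80) {
  stopifnot(minBitScore >= 0, minSimilarity >= 0, minAlignLength >= 0)
  structure(list(minBitScore = minBitScore, minSimilarity = minSimilarity,
                 minAlignLength = minAlignLength),
            class = "SearchThresholds")
}

#' Filter BLAST hits on bit score, similarity and alignment length
#'
#' A hit is retained iff `bit_score >= minBitScore` AND
#' `percent_identity >= minSimilarity` AND
#' `alignment_length >= minAlignLength` (all boundaries inclusive:
#' a 60-bit, 40%-identity hit at the default thresholds passes).
#'
#' @param hits data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `evalue`, `bit_score`.
#' @param thresholds a [searchThresholds()] list.
#' @return the retained rows of `hits`.
#' @export
filterHits <- function(hits, thresholds = searchThresholds()) {
  keep <- hits$bit_score >= thresholds$minBitScore &
    hits$percent_identity >= thresholds$minSimilarity &
    hits$alignment_length >= thresholds$minAlignLength
  hits[keep, , drop = FALSE]
}

.readBlastTab <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bit_score")
  if (!file.size(path)) {
    out <- as.data.frame(setNames(rep(list(character()), 12L), cols))
    out[c(3:12)] <- lapply(out[c(3:12)], as.numeric)
    return(out)
  }
  out <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  names(out) <- cols
  out[3:12] <- lapply(out[3:12], as.numeric)
  out
}

#' Identify initial candidates by BLAST against the bait collection
#'
#' Runs `blastp` with the bait sequences as queries against the subject
#' set, filters the tabular hits with [filterHits()], and returns the set
#' of subject identifiers with at least one surviving hit. Multiple hits
#' per subject collapse to membership.
#'
#' @param subject named `AAStringSet` of subject sequences.
#' @param baits named `AAStringSet` of bait sequences.
#' @param thresholds a [searchThresholds()] list.
#' @param rawFile,filteredFile optional paths to write the raw and filtered
#'   tabular hits.
#' @return character vector of candidate subject ids (possibly empty, with
#'   a warning when no hit passes).
#' @export
blastCandidates <- function(subject, baits, thresholds = searchThresholds(),
                            rawFile = NULL, filteredFile = NULL) {
  if (!length(subject) || !length(baits))
    stop("subject and bait sets must be non-empty")
  wd <- tempfile("blastdb")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  dbFa <- file.path(wd, "subject.fasta")
  qFa <- file.path(wd, "baits.fasta")
  writeFastaFile(subject, dbFa)
  writeFastaFile(baits, qFa)
  .runTool("makeblastdb", c("-in", dbFa, "-dbtype", "prot"))
  tab <- file.path(wd, "hits.tsv")
  .runTool("blastp", c("-query", qFa, "-db", dbFa, "-outfmt", "6",
                       "-evalue", "1e-3", "-out", tab))
  hits <- .readBlastTab(tab)
  if (!is.null(rawFile))
    utils::write.table(hits, rawFile, sep = "\t", quote = FALSE, row.names = FALSE)
  kept <- filterHits(hits, thresholds)
  if (!is.null(filteredFile))
    utils::write.table(kept, filteredFile, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!nrow(kept)) {
    warning("no BLAST hit passed the thresholds; candidate set is empty")
    return(character())
  }
  ids <- unique(kept$subject_id)
  ids[order(match(ids, names(subject)))]
}

#' Identify initial candidates by profile-HMM scan
#'
#' Runs `hmmsearch` with the family profile HMM against the subject set and
#' returns the ids of sequences with a domain hit passing the default
#' inclusion threshold.
#'
#' @param subject named `AAStringSet`.
#' @param domainHmm path to a HMMER profile file.
#' @return character vector of candidate ids, in subject order.
#' @export
hmmerCandidates <- function(subject, domainHmm) {
  if (!length(subject)) return(character())
  hits <- .hmmsearch(domainHmm, subject)
  ids <- unique(hits$target)
  ids[order(match(ids, names(subject)))]
}
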