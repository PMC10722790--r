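# Subfamily-motif screening. Motifs are short profile HMMs (one file per
# motif, filename = motif name); a candidate may carry motifs of several
# subfamilies, and overlapping hits from different motifs are all reported.

#' Scan candidates for subfamily-specific motifs
#'
#' Runs every motif HMM of a collection against the candidates at the
#' scanner's default inclusion threshold. Hits are reported per candidate,
#' ordered by envelope start; the matched subsequence is extracted from the
#' candidate sequence.
#'
#' @param candidates named `AAStringSet`.
#' @param motifCollection either a directory of `.hmm` files or a named
#'   character vector of HMM file paths (names = motif names).
#' @param fastaFile optional path for a FASTA of the extracted motif
#'   subsequences (headers `candidate|motif|start-end`).
#' @return data.frame: `candidate`, `motif`, `score`, `env_start`,
#'   `env_end`, `motif_seq`; zero rows (with a warning) for an empty
#'   collection.
#' @export
scanMotifs <- function(candidates, motifCollection, fastaFile = NULL) {
  paths <- .motifPaths(motifCollection)
  empty <- data.frame(candidate = character(), motif = character(),
                      score = numeric(), env_start = integer(),
                      env_end = integer(), motif_seq = character(),
                      stringsAsFactors = FALSE)
  if (!length(paths)) {
    warning("motif collection is empty")
    return(empty)
  }
  if (anyDuplicated(names(paths))) stop("motif names must be unique")
  res <- list()
  for (motif in names(paths)) {
    hits <- tryCatch(.hmmsearch(paths[[motif]], candidates),
                     error = function(e)
                       stop("malformed motif file '", motif, "': ",
                            conditionMessage(e)))
    if (!nrow(hits)) next
    res[[motif]] <- data.frame(
      candidate = hits$target, motif = motif, score = hits$dom_score,
      env_start = as.integer(hits$env_from),
      env_end = as.integer(hits$env_to), stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out$motif_seq <- vapply(seq_len(nrow(out)), function(i)
    substr(as.character(candidates[[out$candidate[i]]]),
           out$env_start[i], out$env_end[i]), character(1))
  out <- out[order(match(out$candidate, names(candidates)), out$env_start,
                   out$motif), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(fastaFile) && nrow(out)) {
    hdr <- sprintf("%s|%s|%d-%d", out$candidate, out$motif,
                   out$env_start, out$env_end)
    writeFastaFile(setNames(out$motif_seq, hdr), fastaFile)
  }
  out
}

.motifPaths <- function(motifCollection) {
  if (length(motifCollection) == 1L && dir.exists(motifCollection)) {
    files <- list.files(motifCollection, pattern = "\\.hmm$",
                        full.names = TRUE)
    return(setNames(files, sub("\\.hmm$", "", basename(files))))
  }
  if (is.null(names(motifCollection)) && length(motifCollection))
    names(motifCollection) <- sub("\\.hmm$", "", basename(motifCollection))
  motifCollection
}

#' Build one motif HMM from aligned motif instances
#'
#' Utility for extending the motif collection: aligns the supplied motif
#' instances (skipped when already equal-width) and runs `hmmbuild`.
#'
#' @param seqs named `AAStringSet` of motif instances.
#' @param hmmFile output HMM path.
#' @param name motif name stored in the profile.
#' @param alignTool aligner for unaligned input.
#' @return `hmmFile`, invisibly.
#' @export
buildMotifHmm <- function(seqs, hmmFile, name = "motif",
                          alignTool = "mafft") {
  if (length(unique(Biostrings::width(seqs))) != 1L)
    seqs <- alignSequences(seqs, tool = alignTool)
  .hmmbuild(seqs, hmmFile, name = name)
  invisible(hmmFile)
}
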