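# bHLH domain detection and DNA-binding-group prediction. The binding
# rules read residues at fixed positions of the domain's basic region,
# located in the alignment through a reference sequence (the role played by
# AT1G09530 in the shipped annotation): DNA binding needs >= 5 basic
# residues in the basic region, E-box binding needs E at position 9 and R
# at position 12, G-box binding needs H, E, R at positions 5, 9 and 13.

#' Detect the family domain in candidate sequences
#'
#' Runs the profile HMM against every candidate; the best-scoring domain
#' per sequence is kept and its envelope extracted.
#'
#' @param candidates named `AAStringSet`.
#' @param domainHmm path to the profile HMM.
#' @param fastaFile optional path to write the extracted domain sequences.
#' @return data.frame, one row per candidate: `candidate`, `present`,
#'   `env_start`, `env_end` (1-based, `NA` when absent), `domain_seq`.
#' @export
detectDomains <- function(candidates, domainHmm, fastaFile = NULL) {
  hits <- .hmmsearch(domainHmm, candidates)
  out <- data.frame(candidate = names(candidates), present = FALSE,
                    env_start = NA_integer_, env_end = NA_integer_,
                    domain_seq = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    h <- hits[hits$target == out$candidate[i], , drop = FALSE]
    if (!nrow(h)) next
    h <- h[which.max(h$dom_score), ]
    out$present[i] <- TRUE
    out$env_start[i] <- as.integer(h$env_from)
    out$env_end[i] <- as.integer(h$env_to)
    out$domain_seq[i] <- substr(as.character(candidates[[out$candidate[i]]]),
                                h$env_from, h$env_to)
  }
  if (!is.null(fastaFile)) {
    dom <- out[out$present, , drop = FALSE]
    writeFastaFile(setNames(dom$domain_seq, dom$candidate), fastaFile)
  }
  out
}

#' Map reference domain positions to alignment columns
#'
#' The k-th non-gap residue of the reference row, counted from the first
#' residue of its domain, defines domain position k; this returns the
#' alignment column of every domain position. When the alignment was
#' trimmed, pass the trim report from [trimAlignment()] with the
#' *untrimmed* alignment: positions whose column was trimmed away are
#' reported as unavailable (`NA`), and returned columns index the trimmed
#' alignment.
#'
#' @param aln `AAStringSet` alignment containing the reference row.
#' @param referenceId id of the reference row.
#' @param domainStart,domainEnd 1-based residue coordinates of the domain
#'   in the unaligned reference sequence (e.g. the HMM envelope from
#'   [detectDomains()]).
#' @param trimReport optional result of [trimAlignment()] applied to `aln`.
#' @return integer vector, one element per domain position `1..L`; `NA`
#'   where the position fell in a trimmed-away column.
#' @export
mapReferenceColumns <- function(aln, referenceId, domainStart, domainEnd,
                                trimReport = NULL) {
  m <- .alnMatrix(aln)
  if (!referenceId %in% rownames(m))
    stop("reference id missing from alignment: ", referenceId)
  row <- m[referenceId, ]
  resCols <- which(row != "-" & row != ".")
  if (domainEnd > length(resCols))
    stop("domain coordinates exceed the reference sequence length")
  cols <- resCols[domainStart:domainEnd]
  if (!is.null(trimReport)) {
    cols <- match(cols, trimReport$keptColumns)  # NA when trimmed away
  }
  cols
}

#' Predict DNA-binding group for candidate rows of an alignment
#'
#' For each candidate row: counts basic residues (default set `R`, `K`,
#' `H`) over the basic-region columns (domain positions
#' `basicRegionSpan`), reads the residues at domain positions 5, 9, 12 and
#' 13, and applies the three rules. A candidate whose basic region is
#' entirely gapped is flagged unevaluable and all calls are `FALSE`.
#'
#' @param aln `AAStringSet` alignment (the trimmed alignment behind the
#'   final tree).
#' @param columns integer vector from [mapReferenceColumns()] (alignment
#'   column per domain position; `NA` = unavailable).
#' @param candidateIds rows to evaluate.
#' @param basicRegionSpan domain positions forming the basic region
#'   (default `1:16`, the stretch preceding helix 1).
#' @param minBasic minimum basic-residue count for a DNA-binding call
#'   (default 5; exactly 5 passes).
#' @param basicResidues residues counted as basic (default `R`, `K`, `H`).
#' @return data.frame per candidate: `candidate`, `n_basic`, `res5`,
#'   `res9`, `res12`, `res13` (single characters, `"-"` when gapped or
#'   unavailable), `dna_binding`, `ebox_binding`, `gbox_binding`,
#'   `evaluable`.
#' @export
predictBinding <- function(aln, columns, candidateIds,
                           basicRegionSpan = 1:16, minBasic = 5,
                           basicResidues = c("R", "K", "H")) {
  m <- .alnMatrix(aln)
  missing <- setdiff(candidateIds, rownames(m))
  if (length(missing))
    stop("candidates missing from alignment: ", paste(missing, collapse = ", "))
  span <- basicRegionSpan[basicRegionSpan <= length(columns)]
  basicCols <- columns[span]
  basicCols <- basicCols[!is.na(basicCols)]
  posCol <- function(p) if (p <= length(columns)) columns[p] else NA_integer_
  resAt <- function(rowChars, p) {
    cl <- posCol(p)
    if (is.na(cl)) return("-")
    r <- rowChars[cl]
    if (r %in% c("-", ".")) "-" else r
  }
  rows <- lapply(candidateIds, function(cd) {
    rc <- m[cd, ]
    region <- rc[basicCols]
    evaluable <- length(region) > 0 && any(region != "-" & region != ".")
    nBasic <- sum(region %in% basicResidues)
    r5 <- resAt(rc, 5L); r9 <- resAt(rc, 9L)
    r12 <- resAt(rc, 12L); r13 <- resAt(rc, 13L)
    dna <- evaluable && nBasic >= minBasic
    ebox <- evaluable && r9 == "E" && r12 == "R"
    gbox <- evaluable && r5 == "H" && r9 == "E" && r13 == "R"
    data.frame(candidate = cd, n_basic = nBasic, res5 = r5, res9 = r9,
               res12 = r12, res13 = r13, dna_binding = dna,
               ebox_binding = ebox, gbox_binding = gbox,
               evaluable = evaluable, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
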