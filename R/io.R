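#' @importFrom Biostrings readAAStringSet readDNAStringSet writeXStringSet
#'   AAStringSet DNAStringSet translate width subseq
NULL

# Characters that break Newick files, HMMER tables or shell quoting when
# they occur in sequence identifiers: whitespace plus ; : , ( ) [ ] ' "
# (POSIX class: literal ] first, literal [ inside)
.FORBIDDEN_ID_RE <- "[][()[:space:];:,'\"]"

#' Read protein (or coding) sequences
#'
#' Reads a FASTA file into an [Biostrings::AAStringSet]. Identifiers are the
#' full header lines (everything after `>`), untouched; cleaning is a
#' separate, reversible step ([sanitizeIdentifiers()]). Coding sequences are
#' translated in frame 1 with a trailing stop codon trimmed.
#'
#' @param path FASTA file.
#' @param type `"protein"` (default), `"cds"` (translate frame 1), or
#'   `"auto"` (treat as CDS when every residue is in `ACGTUN-`).
#' @return `AAStringSet`, one element per FASTA record, order preserved.
#'   Residues are uppercased. Errors on an empty file or duplicate headers;
#'   warns on residues outside the amino-acid alphabet (`X` allowed).
#' @export
readProteins <- function(path, type = c("protein", "cds", "auto")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no sequences in ", path)
  if (anyDuplicated(names(raw)))
    stop("duplicate headers in ", path, ": ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  chr <- toupper(as.character(raw))
  if (any(nchar(chr) == 0L)) stop("zero-length sequence in ", path)
  if (type == "auto") {
    nuc <- all(!grepl("[^ACGTUN-]", chr))
    type <- if (nuc) "cds" else "protein"
  }
  if (type == "cds") {
    dna <- Biostrings::DNAStringSet(gsub("U", "T", chr))
    aa <- suppressWarnings(
      Biostrings::translate(dna, if.fuzzy.codon = "solve"))
    chr <- sub("\\*$", "", as.character(aa))
    if (any(nchar(chr) == 0L)) stop("translation produced an empty sequence")
  } else {
    bad <- grepl("[^ARNDCQEGHILKMFPSTWYVXBZJUO*-]", chr)
    if (any(bad))
      warning("non-amino-acid characters in: ",
              paste(names(raw)[bad], collapse = ", "))
  }
  out <- Biostrings::AAStringSet(chr)
  names(out) <- names(raw)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs an `AAStringSet` (or coercible named character vector).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFastaFile <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Clean sequence identifiers, keeping a reversible mapping
#'
#' Replaces every forbidden character (whitespace and the Newick-reserved
#' set `; : , ( ) [ ] ' "`) in each identifier with an underscore and
#' enforces uniqueness by appending `_<n>` on collision. The returned map
#' restores the original headers in all final outputs.
#'
#' @param seqs named `AAStringSet` (or any named vector).
#' @return list with `seqs` (renamed input) and `map`, a data.frame with
#'   columns `sanitized` and `original` (a bijection; sanitize is
#'   idempotent, so already-clean unique ids map to themselves).
#' @examples
#' s <- Biostrings::AAStringSet(c("AT1G09530.1 note" = "MKRR", "a;b" = "MAAK"))
#' sanitizeIdentifiers(s)$map
#' @export
sanitizeIdentifiers <- function(seqs) {
  orig <- names(seqs)
  if (is.null(orig)) stop("sequences must be named")
  clean <- gsub(.FORBIDDEN_ID_RE, "_", orig)
  # deterministic collision suffixes, in input order
  out <- character(length(clean))
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(clean)) {
    id <- clean[i]
    if (!is.null(seen[[id]])) {
      n <- 0L
      repeat {
        n <- n + 1L
        cand <- paste0(id, "_", n)
        if (is.null(seen[[cand]])) { id <- cand; break }
      }
    }
    seen[[id]] <- TRUE
    out[i] <- id
  }
  names(seqs) <- out
  list(seqs = seqs,
       map = data.frame(sanitized = out, original = orig,
                        stringsAsFactors = FALSE))
}

#' Write / read the identifier mapping file
#'
#' Two-column tab-separated file (`sanitized_id`, `original_id`).
#' @param map data.frame from [sanitizeIdentifiers()].
#' @param path file path.
#' @return `writeIdentifierMap`: `path` invisibly; `readIdentifierMap`:
#'   the mapping data.frame.
#' @export
writeIdentifierMap <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("sanitized_id", "original_id"))
  invisible(path)
}

#' @rdname writeIdentifierMap
#' @export
readIdentifierMap <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character", quote = "",
                         comment.char = "")
  names(m) <- c("sanitized", "original")
  m
}

#' Restore original identifiers
#'
#' @param ids character vector of sanitized ids.
#' @param map mapping data.frame (`sanitized`, `original`).
#' @return character vector of original ids; ids absent from the map are
#'   returned unchanged (baits and references are never sanitized).
#' @export
restoreIdentifiers <- function(ids, map) {
  i <- match(ids, map$sanitized)
  out <- ids
  out[!is.na(i)] <- map$original[i[!is.na(i)]]
  out
}

#' Read a reference annotation table
#'
#' Tab-separated table with columns `id`, `description`, `alt_name`,
#' `subfamily` (header required; extra columns ignored).
#'
#' @param path TSV file.
#' @return data.frame with those four character columns.
#' @export
readReferenceTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  need <- c("id", "description", "alt_name", "subfamily")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("reference table missing columns: ", paste(miss, collapse = ", "))
  tab[need]
}

#' Validate pipeline inputs before running
#'
#' Checks performed before any compute: all referenced files exist and
#' parse; every reference-table identifier occurs in the bait collection or
#' the landmark file; the bait and outgroup sets are disjoint. Failures
#' list every offending identifier.
#'
#' @param config a list from [pipelineConfig()].
#' @return the config, invisibly, with parsed `baits`, `outgroup`,
#'   `reference` attached under `parsed`.
#' @export
validateInputs <- function(config) {
  for (f in c("subject", "baits", "outgroup")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("missing input file (", f, "): ", config[[f]])
  }
  baits <- readProteins(config$baits)
  outgr <- readProteins(config$outgroup)
  overlap <- intersect(names(baits), names(outgr))
  if (length(overlap))
    stop("identifiers present in both bait and outgroup files: ",
         paste(overlap, collapse = ", "))
  ref <- NULL
  if (!is.null(config$referenceTable)) {
    ref <- readReferenceTable(config$referenceTable)
    pool <- names(baits)
    if (!is.null(config$landmarks) && file.exists(config$landmarks))
      pool <- union(pool, names(readProteins(config$landmarks)))
    absent <- setdiff(ref$id, pool)
    if (length(absent))
      stop("reference ids absent from the bait collection (and landmarks): ",
           paste(absent, collapse = ", "))
  }
  config$parsed <- list(baits = baits, outgroup = outgr, reference = ref)
  invisible(config)
}
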