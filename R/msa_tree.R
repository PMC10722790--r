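# Alignment and tree construction. External aligners and tree builders are
# wrapped behind one adapter contract (write input, run, read output, check
# exit code); a built-in neighbour-joining method gives a fast,
# deterministic tree without any external tool.

#' Align protein sequences
#'
#' Global multiple sequence alignment with MAFFT (default) or Muscle5,
#' whichever is requested and on the PATH. The adapter never alters
#' sequence content: removing the gaps from any output row restores the
#' input sequence exactly.
#'
#' @param seqs named `AAStringSet`, at least 2 sequences.
#' @param tool `"mafft"` or `"muscle"`.
#' @return an `AAStringSet` of equal-width gapped rows, same id set as the
#'   input.
#' @export
alignSequences <- function(seqs, tool = c("mafft", "muscle")) {
  tool <- match.arg(tool)
  if (length(seqs) < 2L) stop("alignment needs at least 2 sequences")
  inFa <- tempfile(fileext = ".fasta")
  outFa <- tempfile(fileext = ".afa")
  on.exit(unlink(c(inFa, outFa)), add = TRUE)
  writeFastaFile(seqs, inFa)
  if (tool == "mafft") {
    .runToolToFile("mafft", c("--auto", "--anysymbol", "--quiet", inFa),
                   outFa)
  } else {
    .runTool("muscle", c("-align", inFa, "-output", outFa))
  }
  aln <- Biostrings::readAAStringSet(outFa)
  aln <- Biostrings::AAStringSet(toupper(as.character(aln)))
  if (!setequal(names(aln), names(seqs)))
    stop("aligner changed the identifier set")
  aln[names(seqs)]
}

#' Trim alignment columns by occupancy
#'
#' Removes every column whose fraction of non-gap characters is below
#' `minOccupancy`; a column at exactly the threshold is kept ("less than
#' 10% occupancy" is removed). `-` and `.` count as gaps; `X` counts as
#' occupied. Row order is preserved; rows that become all-gap are retained.
#'
#' @param aln `AAStringSet` of equal-width rows.
#' @param minOccupancy minimum kept occupancy fraction (default 0.10).
#' @return list with `alignment` (trimmed `AAStringSet`), `keptColumns`
#'   (strictly increasing original column indices) and `nRemoved`.
#' @export
trimAlignment <- function(aln, minOccupancy = 0.10) {
  m <- .alnMatrix(aln)
  occ <- colMeans(m != "-" & m != ".")
  keep <- which(occ >= minOccupancy)
  trimmed <- if (length(keep)) {
    apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  } else {
    setNames(rep("", nrow(m)), rownames(m))
  }
  out <- Biostrings::AAStringSet(trimmed)
  names(out) <- rownames(m)
  list(alignment = out, keptColumns = keep, nRemoved = ncol(m) - length(keep))
}

.alnMatrix <- function(aln) {
  if (is(aln, "XStringSet")) {
    w <- Biostrings::width(aln)
    if (length(unique(w)) != 1L) stop("rows have unequal width")
    chr <- as.character(aln)
  } else {
    chr <- aln
    if (length(unique(nchar(chr))) != 1L) stop("rows have unequal width")
  }
  m <- do.call(rbind, strsplit(chr, ""))
  rownames(m) <- names(chr)
  m
}

#' Build a phylogenetic tree from a trimmed alignment
#'
#' `"fasttree"` runs FastTree2 with the WAG model (`-wag`); `"raxml"` runs
#' RAxML-NG with `LG+G`; `"nj"` is a built-in neighbour-joining tree on
#' pairwise p-distances (deterministic, no external tool). The result is
#' returned unrooted with any negative NJ branch lengths clamped to zero.
#'
#' @param aln `AAStringSet` of equal-width rows (>= 4 for external tools,
#'   >= 3 for NJ).
#' @param tool `"fasttree"`, `"nj"`, or `"raxml"`.
#' @param newickFile optional path to also write the tree.
#' @param seed integer seed passed to tools that accept one.
#' @return an unrooted `ape::phylo` whose tip set equals the alignment ids.
#' @export
buildTree <- function(aln, tool = c("fasttree", "nj", "raxml"),
                      newickFile = NULL, seed = 1L) {
  tool <- match.arg(tool)
  if (anyDuplicated(names(aln))) stop("duplicate leaf labels")
  tr <- switch(tool,
    fasttree = .fasttreeTree(aln),
    raxml = .raxmlTree(aln, seed),
    nj = .njTree(aln))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (ape::is.rooted(tr) && length(tr$tip.label) >= 3L)
    tr <- ape::unroot(tr)
  if (!setequal(tr$tip.label, names(aln)))
    stop("tree tool changed the leaf set")
  if (!is.null(newickFile)) ape::write.tree(tr, newickFile)
  tr
}

.fasttreeTree <- function(aln) {
  inFa <- tempfile(fileext = ".afa")
  outNwk <- tempfile(fileext = ".nwk")
  on.exit(unlink(c(inFa, outNwk)), add = TRUE)
  writeFastaFile(aln, inFa)
  .runToolToFile("fasttree", c("-quiet", "-nopr", "-wag", inFa), outNwk)
  ape::read.tree(outNwk)
}

.raxmlTree <- function(aln, seed) {
  wd <- tempfile("raxml")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  inFa <- file.path(wd, "aln.fasta")
  writeFastaFile(aln, inFa)
  .runTool("raxml-ng", c("--msa", inFa, "--model", "LG+G",
                         "--seed", as.character(seed), "--threads", "1"))
  ape::read.tree(file.path(wd, "aln.fasta.raxml.bestTree"))
}

# p-distance (fraction of mismatching residues over shared non-gap
# columns) + neighbour joining; njs() handles missing overlaps.
.njTree <- function(aln) {
  m <- .alnMatrix(aln)
  n <- nrow(m)
  if (n < 3L) stop("NJ tree needs at least 3 sequences")
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      d[i, j] <- d[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 1
    }
  }
  if (n == 3L) {
    # NJ is defined for >= 4 tips; solve the 3-leaf star exactly
    v <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    txt <- sprintf("(%s:%f,%s:%f,%s:%f);", rownames(m)[1], max(v[1], 0),
                   rownames(m)[2], max(v[2], 0), rownames(m)[3], max(v[3], 0))
    return(ape::read.tree(text = txt))
  }
  ape::njs(as.dist(d))
}
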