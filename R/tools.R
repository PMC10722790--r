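# Thin adapters around external command-line tools. Every invocation goes
# through .runTool so the exact command line, exit status and captured
# output are available to the run manifest and to error messages.

.toolAvailable <- function(exe) nzchar(Sys.which(exe))

.runTool <- function(exe, args, logFile = NULL) {
  if (!.toolAvailable(exe)) stop("executable not found on PATH: ", exe)
  out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (is.null(status)) status <- 0L
  rec <- list(command = paste(c(exe, args), collapse = " "),
              status = status, output = out)
  if (!is.null(logFile))
    writeLines(c(rec$command, paste0("exit: ", status), out), logFile)
  if (status != 0L)
    stop(exe, " failed (exit ", status, "):\n",
         paste(utils::tail(out, 20L), collapse = "\n"))
  invisible(rec)
}

# Run a tool whose primary output goes to stdout, redirected to a file;
# stderr is captured to a scratch file and surfaced on failure.
.runToolToFile <- function(exe, args, outFile) {
  if (!.toolAvailable(exe)) stop("executable not found on PATH: ", exe)
  errFile <- tempfile(fileext = ".log")
  on.exit(unlink(errFile), add = TRUE)
  status <- suppressWarnings(
    system2(exe, args, stdout = outFile, stderr = errFile))
  if (status != 0L || !file.exists(outFile)) {
    err <- if (file.exists(errFile)) readLines(errFile) else character()
    stop(exe, " failed (exit ", status, "):\n",
         paste(utils::tail(err, 20L), collapse = "\n"))
  }
  invisible(list(command = paste(c(exe, args), collapse = " "),
                 status = status))
}

# Parse a HMMER --domtblout file into a data.frame (one row per domain).
.readDomTbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  cols <- c("target", "tacc", "tlen", "query", "qacc", "qlen",
            "seq_evalue", "seq_score", "seq_bias", "dom_n", "dom_total",
            "c_evalue", "i_evalue", "dom_score", "dom_bias",
            "hmm_from", "hmm_to", "ali_from", "ali_to",
            "env_from", "env_to", "acc")
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
    num <- c(3, 6:21)
    out[num] <- lapply(out[num], as.numeric)
    return(out)
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  m <- t(vapply(parts, function(p) p[1:22], character(22)))
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  num <- c("tlen", "qlen", "seq_evalue", "seq_score", "seq_bias", "dom_n",
           "dom_total", "c_evalue", "i_evalue", "dom_score", "dom_bias",
           "hmm_from", "hmm_to", "ali_from", "ali_to", "env_from", "env_to",
           "acc")
  out[num] <- lapply(out[num], as.numeric)
  out
}

# hmmsearch of one profile HMM against a sequence set; returns the domain
# table restricted to hits passing the default inclusion thresholds
# (full-sequence E-value <= incE and per-domain independent E-value
# <= incDomE, HMMER's default inclusion cutoffs).
.hmmsearch <- function(hmmFile, seqs, incE = 0.01, incDomE = 0.01,
                       logFile = NULL) {
  if (!file.exists(hmmFile)) stop("HMM file not found: ", hmmFile)
  if (!any(grepl("^HMMER", readLines(hmmFile, n = 1L))))
    stop("not a HMMER profile file: ", hmmFile)
  fa <- tempfile(fileext = ".fasta")
  on.exit(unlink(fa), add = TRUE)
  writeFastaFile(seqs, fa)
  tbl <- tempfile(fileext = ".domtbl")
  on.exit(unlink(tbl), add = TRUE)
  .runTool("hmmsearch", c("--domtblout", tbl, "--noali", hmmFile, fa),
           logFile = logFile)
  hits <- .readDomTbl(tbl)
  hits[hits$seq_evalue <= incE & hits$i_evalue <= incDomE, , drop = FALSE]
}

# Build a profile HMM from an aligned FASTA (equal-width rows).
.hmmbuild <- function(alignedSeqs, hmmFile, name = "profile") {
  fa <- tempfile(fileext = ".afa")
  on.exit(unlink(fa), add = TRUE)
  writeFastaFile(alignedSeqs, fa)
  .runTool("hmmbuild", c("--amino", "-n", name, hmmFile, fa))
  invisible(hmmFile)
}
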