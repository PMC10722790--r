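# The mini reference bundle (bait/outgroup FASTAs, reference table, domain
# and motif HMMs) is deterministic but costs a few hmmbuild calls, so it
# is built once per test session and cached.
.bundleEnv <- new.env(parent = emptyenv())

testBundle <- function() {
  if (is.null(.bundleEnv$bundle)) {
    dir <- file.path(tempdir(), "bhlhfinder-test-bundle")
    .bundleEnv$bundle <- miniReferenceBundle(dir, seed = 42L)
  }
  .bundleEnv$bundle
}

# small subject FASTA on disk for pipeline tests
writeToyProteomeFasta <- function(tp) {
  fa <- tempfile(fileext = ".fasta")
  writeFastaFile(tp$seqs, fa)
  fa
}
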