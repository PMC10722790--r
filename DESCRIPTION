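Package: bHLHfinder
Title: Identification, Phylogenetic Classification and Annotation of
    Plant bHLH Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automatic identification and annotation of basic
    helix-loop-helix (bHLH) transcription factors in plant protein or
    coding-sequence sets. Initial candidates are found by BLAST against a
    curated bait collection or by a profile-HMM scan, then classified as
    ingroup (bHLH) or outgroup by the composition of their nearest bait
    neighbours in a phylogenetic tree, in two passes. Final candidates are
    assigned an ortholog bait by minimum tree distance, annotated from a
    reference table, checked for the bHLH domain, scored for DNA-, E-box-
    and G-box-binding from basic-region residues, screened for
    subfamily-specific motifs, and (for transcriptome assemblies)
    collapsed into per-clade representatives. External aligners, tree
    builders and HMMER are wrapped behind small adapters; a deterministic
    synthetic-fixture generator makes the whole pipeline testable at toy
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
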