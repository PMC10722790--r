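# Deterministic synthetic fixtures: toy proteomes with planted bHLH-like
# domains, labelled trees, and a mini bait/outgroup/reference bundle, so
# every stage of the pipeline can be exercised without any real data. All
# sequence material here is synthetic; the 60-aa domain consensus below
# mimics the architecture of a plant bHLH domain (16-residue basic region
# with H/E/R at positions 5, 9, 12-13, then helix-loop-helix) but is not a
# natural sequence.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

.BASIC_REGIONS <- c(
  gbox = "RRNAHSELERRRREKI",  # H5 E9 R12 R13, 8 basic residues
  ebox = "RRNANSELERRRLEKI",  # E9 R12 but N5, L13 -> E-box, not G-box
  none = "PSNAPSELEPSPQDSI")  # proline-rich atypical HLH, 0 basic residues

.HLH_REGION <- paste0("AAEVLNLSRSLLDLV", "PGTNGKS", "VILDDAIEYIKSLQNELQELME")

# fixed substitutions distinguishing the three synthetic subfamilies
.SUBFAMILY_SUBS <- list(
  A = character(),
  B = c(`18` = "G", `22` = "T", `26` = "K", `40` = "N", `46` = "M", `52` = "F"),
  C = c(`19` = "W", `24` = "C", `30` = "Q", `42` = "S", `50` = "T", `56` = "Y"))

.MOTIF_CONSENSUS <- c(
  `S-A` = "WPDFNSMQEYWGDTLHKACW",
  `S-B` = "CYGNPWDKEMSFTQYLVRGC",
  `S-C` = "FWEPTGYNDMCKQSLAHWIF")

# Deterministic per-subfamily protein scaffolds (N-terminal flank, linker
# between domain and motif, C-terminal tail). Members of a subfamily are
# full-length homologs -- as real gene-family members are -- so trees see
# signal beyond the domain itself. Scaffold seeds are fixed constants so
# bait bundle and toy proteomes agree regardless of user seeds.
.SCAFFOLD_SEEDS <- c(A = 760001L, B = 760002L, C = 760003L, OUT = 760009L)

.scaffold <- function(key) {
  .withSeed(.SCAFFOLD_SEEDS[[key]], {
    list(n = .randAA(45L), linker = .randAA(15L), c = .randAA(25L))
  })
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

.randAA <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")

# substitute positions of `s` (chosen from `positions`) at `rate`,
# always to a different residue
.mutateAt <- function(s, rate, positions) {
  ch <- strsplit(s, "")[[1]]
  hit <- positions[runif(length(positions)) < rate]
  for (p in hit) {
    ch[p] <- sample(setdiff(.AA20, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' The synthetic domain consensus
#'
#' @param subfamily `"A"`, `"B"` or `"C"`; subfamilies differ by six fixed
#'   substitutions in the helix-loop-helix region.
#' @param profile basic-region variant: `"gbox"` (H5/E9/R12/R13, 8 basic
#'   residues), `"ebox"` (E9/R12 only) or `"none"` (atypical, proline-rich,
#'   0 basic residues).
#' @return a 60-character string: 16-residue basic region + 44-residue
#'   helix-loop-helix region.
#' @export
domainConsensus <- function(subfamily = c("A", "B", "C"),
                            profile = c("gbox", "ebox", "none")) {
  subfamily <- match.arg(subfamily)
  profile <- match.arg(profile)
  ch <- strsplit(paste0(.BASIC_REGIONS[[profile]], .HLH_REGION), "")[[1]]
  subs <- .SUBFAMILY_SUBS[[subfamily]]
  if (length(subs)) ch[as.integer(names(subs))] <- subs
  paste(ch, collapse = "")
}

# assemble one family member on its subfamily scaffold:
# N-flank + domain + linker + motif (optional) + C-tail, each mutated,
# then 0..trimMax residues trimmed off either end (isoform-like length
# variation). Returns the sequence plus domain/motif coordinates.
.assembleMember <- function(subf, profile, mutationRate, withMotif = TRUE,
                            domainMutablePositions = 17:60, trimMax = 15L) {
  sc <- .scaffold(subf)
  dom <- .mutateAt(domainConsensus(subf, profile), mutationRate,
                   domainMutablePositions)
  motif <- if (withMotif)
    .mutateAt(.MOTIF_CONSENSUS[[paste0("S-", subf)]], mutationRate, 1:20)
  else ""
  nf <- .mutateAt(sc$n, mutationRate, seq_len(nchar(sc$n)))
  lk <- .mutateAt(sc$linker, mutationRate, seq_len(nchar(sc$linker)))
  ct <- .mutateAt(sc$c, mutationRate, seq_len(nchar(sc$c)))
  seq <- paste0(nf, dom, lk, motif, ct)
  kN <- sample(0:trimMax, 1L)
  kC <- sample(0:trimMax, 1L)
  seq <- substr(seq, kN + 1L, nchar(seq) - kC)
  list(seq = seq, dom = dom,
       domain_start = nchar(sc$n) + 1L - kN,
       domain_end = nchar(sc$n) + 60L - kN,
       motif_start = if (withMotif) nchar(sc$n) + 60L + nchar(sc$linker) + 1L - kN
                     else NA_integer_,
       motif_end = if (withMotif) nchar(sc$n) + 60L + nchar(sc$linker) + 20L - kN
                   else NA_integer_)
}

#' Generate a toy proteome with planted domains and a truth table
#'
#' `nBhlh` sequences are synthetic family members: each is built on its
#' subfamily's shared protein scaffold (subfamilies A-C cycle) and embeds
#' a copy of the synthetic domain consensus with the binding profile
#' cycling over `profiles`. Random substitutions hit the scaffold and the
#' helix-loop-helix region but never the basic region or the
#' binding-diagnostic positions, so the binding truth stays exact; ends
#' are trimmed by 0-15 residues for isoform-like length variation.
#' `nDecoy` sequences are uniform-random background with no domain. Same
#' arguments and seed give byte-identical output.
#'
#' @param nBhlh,nDecoy counts of planted and decoy sequences.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param mutationRate per-site substitution rate outside the protected
#'   basic region (default 0.08).
#' @param lengthRange decoy length range in residues (default 130-170,
#'   matching the planted proteins).
#' @param profiles binding profiles cycled over the planted sequences.
#' @param withMotifs plant each sequence's subfamily motif downstream of
#'   the domain (default `TRUE`; real bHLHs typically carry subfamily
#'   motifs outside the domain).
#' @return list: `seqs` (named `AAStringSet`) and `truth` (data.frame with
#'   id, label, subfamily, profile, domain_start/end, n_basic,
#'   res5/9/12/13, dna/ebox/gbox truth, and motif coordinates when
#'   planted).
#' @export
makeToyProteome <- function(nBhlh = 10L, nDecoy = 10L, seed = 1L,
                            mutationRate = 0.08, lengthRange = c(130L, 170L),
                            profiles = c("gbox", "ebox", "none"),
                            withMotifs = TRUE) {
  stopifnot(mutationRate >= 0, mutationRate <= 1)
  .withSeed(seed, {
    subfams <- c("A", "B", "C")
    seqs <- character(0)
    truth <- list()
    for (i in seq_len(nBhlh)) {
      prof <- profiles[((i - 1L) %% length(profiles)) + 1L]
      subf <- subfams[((i - 1L) %% 3L) + 1L]
      mem <- .assembleMember(subf, prof, mutationRate, withMotifs)
      id <- sprintf("PLANT%03d", i)
      seqs[id] <- mem$seq
      region <- strsplit(substr(mem$dom, 1L, 16L), "")[[1]]
      nBasic <- sum(region %in% c("R", "K", "H"))
      truth[[id]] <- data.frame(
        id = id, label = "bhlh", subfamily = paste0("S-", subf),
        profile = prof, domain_start = mem$domain_start,
        domain_end = mem$domain_end, n_basic = nBasic,
        res5 = region[5], res9 = region[9], res12 = region[12],
        res13 = region[13],
        dna_binding = nBasic >= 5L,
        ebox_binding = region[9] == "E" && region[12] == "R",
        gbox_binding = region[5] == "H" && region[9] == "E" &&
          region[13] == "R",
        motif = if (withMotifs) paste0("motif_S-", subf) else "",
        motif_start = mem$motif_start, motif_end = mem$motif_end,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nDecoy)) {
      id <- sprintf("DECOY%03d", i)
      seqs[id] <- .randAA(sample(lengthRange[1]:lengthRange[2], 1L))
      truth[[id]] <- data.frame(
        id = id, label = "decoy", subfamily = "", profile = "",
        domain_start = NA_integer_, domain_end = NA_integer_,
        n_basic = NA_integer_, res5 = "", res9 = "", res12 = "", res13 = "",
        dna_binding = FALSE, ebox_binding = FALSE, gbox_binding = FALSE,
        motif = "", motif_start = NA_integer_, motif_end = NA_integer_,
        stringsAsFactors = FALSE)
    }
    out <- Biostrings::AAStringSet(seqs)
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(seqs = out, truth = truth)
  })
}

#' Random labelled tree
#'
#' Random additive topology ([ape::rtree()] with uniform branch lengths,
#' unrooted) whose leaves are randomly assigned candidate / ingroup-bait /
#' outgroup-bait roles. Reproducible from the seed.
#'
#' @param nCandidates,nIngroup,nOutgroup leaf counts per role.
#' @param seed integer seed.
#' @return a [LabeledTree-class].
#' @export
randomLabeledTree <- function(nCandidates = 4L, nIngroup = 6L,
                              nOutgroup = 4L, seed = 1L) {
  n <- nCandidates + nIngroup + nOutgroup
  stopifnot(n >= 3L)
  .withSeed(seed, {
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.05, 1))
    labels <- c(sprintf("CAND%02d", seq_len(nCandidates)),
                sprintf("IN%02d", seq_len(nIngroup)),
                sprintf("OUT%02d", seq_len(nOutgroup)))
    roles <- c(rep("candidate", nCandidates),
               rep("ingroup_bait", nIngroup),
               rep("outgroup_bait", nOutgroup))
    perm <- sample(n)
    tr$tip.label <- labels[perm]
    labeledTree(tr, setNames(roles[perm], labels[perm]))
  })
}

#' Write the mini reference bundle
#'
#' A self-consistent toy analogue of the pipeline's curated inputs: 30
#' synthetic baits (10 per subfamily, each carrying its subfamily's domain
#' variant and motif), 10 outgroup sequences carrying a heavily diverged
#' domain (alignable, but phylogenetically distinct), a reference table
#' covering every bait, a domain profile HMM built from mutated consensus
#' copies, and one motif HMM per subfamily. Bait `BAIT_A01` carries the
#' unmutated consensus and serves as the position anchor for binding
#' prediction (the role AT1G09530 plays for real data).
#'
#' @param dir output directory (created).
#' @param seed integer seed.
#' @return list of paths (`baits`, `outgroup`, `referenceTable`,
#'   `domainHmm`, `motifDir`, `referenceId`) plus the parsed `baitSeqs`,
#'   `outgroupSeqs`, `reference` table.
#' @export
miniReferenceBundle <- function(dir = tempfile("bundle"), seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  motifDir <- file.path(dir, "motifs")
  dir.create(motifDir, showWarnings = FALSE)
  .withSeed(seed, {
    baits <- character(0)
    ref <- list()
    for (subf in c("A", "B", "C")) {
      for (i in 1:10) {
        id <- sprintf("BAIT_%s%02d", subf, i)
        if (subf == "A" && i == 1L) {
          # the position anchor: exact scaffold + exact consensus domain
          mem <- .assembleMember(subf, "gbox", 0, trimMax = 0L)
        } else {
          mem <- .assembleMember(subf, "gbox", 0.03)
        }
        baits[id] <- mem$seq
        ref[[id]] <- data.frame(
          id = id,
          description = sprintf("synthetic bHLH, subfamily S-%s, member %d",
                                subf, i),
          alt_name = sprintf("Syn%s-%d", subf, i),
          subfamily = paste0("S-", subf), stringsAsFactors = FALSE)
      }
    }
    outgrp <- character(0)
    # outgroup: its own scaffold plus a heavily diverged domain copy --
    # alignable to the family (BLAST still finds it) but phylogenetically
    # clearly outside the three subfamilies
    outSc <- .scaffold("OUT")
    for (i in 1:10) {
      id <- sprintf("OUTG%02d", i)
      dom <- .mutateAt(domainConsensus("A", "gbox"), 0.45, 1:60)
      outgrp[id] <- paste0(
        .mutateAt(outSc$n, 0.05, 1:45), dom,
        .mutateAt(paste0(outSc$linker, outSc$c), 0.05, 1:40))
    }
    baitSeqs <- Biostrings::AAStringSet(baits)
    outgroupSeqs <- Biostrings::AAStringSet(outgrp)
    reference <- do.call(rbind, ref)
    rownames(reference) <- NULL

    baitsFa <- file.path(dir, "baits.fasta")
    outFa <- file.path(dir, "outgroup.fasta")
    refTsv <- file.path(dir, "reference.tsv")
    writeFastaFile(baitSeqs, baitsFa)
    writeFastaFile(outgroupSeqs, outFa)
    utils::write.table(reference, refTsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    # domain HMM from 24 lightly mutated consensus copies (8 per
    # subfamily); equal length, so the stack is already an alignment
    copies <- character(0)
    for (subf in c("A", "B", "C")) {
      for (i in 1:8) {
        copies[sprintf("seed_%s%02d", subf, i)] <-
          .mutateAt(domainConsensus(subf, "gbox"), 0.04, 17:60)
      }
    }
    domainHmm <- file.path(dir, "bhlh_domain.hmm")
    .hmmbuild(Biostrings::AAStringSet(copies), domainHmm, name = "bHLH_domain")

    for (subf in c("A", "B", "C")) {
      inst <- character(0)
      for (i in 1:15) {
        inst[sprintf("m%02d", i)] <-
          .mutateAt(.MOTIF_CONSENSUS[[paste0("S-", subf)]], 0.04, 1:20)
      }
      .hmmbuild(Biostrings::AAStringSet(inst),
                file.path(motifDir, sprintf("motif_S-%s.hmm", subf)),
                name = sprintf("motif_S-%s", subf))
    }

    list(baits = baitsFa, outgroup = outFa, referenceTable = refTsv,
         domainHmm = domainHmm, motifDir = motifDir,
         referenceId = "BAIT_A01", baitSeqs = baitSeqs,
         outgroupSeqs = outgroupSeqs, reference = reference)
  })
}

#' Count sequences and table rows of a downloaded reference bundle
#'
#' Checks an externally obtained curated bundle (complete baits, optimized
#' baits, outgroup, optimized outgroup FASTA files and the annotation
#' table) by counting FASTA records and table data rows.
#'
#' @param dir directory containing `baits.fasta`, `baits_optimized.fasta`,
#'   `outgroup.fasta`, `outgroup_optimized.fasta`, `annotation.tsv`.
#' @return named integer vector of the five counts.
#' @export
countReferenceBundle <- function(dir) {
  need <- c(baits = "baits.fasta", baits_optimized = "baits_optimized.fasta",
            outgroup = "outgroup.fasta",
            outgroup_optimized = "outgroup_optimized.fasta")
  counts <- vapply(need, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NA_integer_)
    length(Biostrings::fasta.seqlengths(p))
  }, integer(1))
  tab <- file.path(dir, "annotation.tsv")
  counts["annotation_rows"] <- if (file.exists(tab))
    nrow(utils::read.table(tab, sep = "\t", header = TRUE, quote = "",
                           comment.char = "")) else NA_integer_
  counts
}
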