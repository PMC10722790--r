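test_that("planted domains are recovered with accurate envelopes", {
  b <- testBundle()
  tp <- makeToyProteome(9, 0, seed = 81, profiles = "gbox")
  dom <- detectDomains(tp$seqs, b$domainHmm)
  expect_true(all(dom$present))
  for (i in seq_len(nrow(dom))) {
    truth <- tp$truth[tp$truth$id == dom$candidate[i], ]
    expect_lte(abs(dom$env_start[i] - truth$domain_start), 3)
    expect_lte(abs(dom$env_end[i] - truth$domain_end), 3)
    # extracted domain equals the subject substring at the envelope
    expect_identical(dom$domain_seq[i],
                     substr(as.character(tp$seqs[[dom$candidate[i]]]),
                            dom$env_start[i], dom$env_end[i]))
  }
})

test_that("random sequences yield no domain and two plants yield the best one", {
  b <- testBundle()
  decoys <- makeToyProteome(0, 100, seed = 82)$seqs
  dom <- detectDomains(decoys, b$domainHmm)
  expect_false(any(dom$present))

  # one exact consensus copy and one degraded copy: the exact one wins
  set.seed(83)
  bg <- paste(sample(c("G", "S", "T", "P", "W"), 260, replace = TRUE),
              collapse = "")
  exact <- domainConsensus("A", "gbox")
  ch <- strsplit(exact, "")[[1]]
  idx <- seq(2, 60, by = 4)
  ch[idx] <- "G"  # degrade ~25% of positions
  weak <- paste(ch, collapse = "")
  twoPlant <- paste0(substr(bg, 1, 40), weak, substr(bg, 41, 140), exact,
                     substr(bg, 141, 260))
  dd <- detectDomains(Biostrings::AAStringSet(c(dbl = twoPlant)), b$domainHmm)
  expect_true(dd$present)
  expect_lte(abs(dd$env_start - 201), 3)  # the exact copy at 141+60+1
})

test_that("reference domain positions map through gaps and trimming", {
  # gap-free reference starting at column 1: position p -> column p
  aln1 <- Biostrings::AAStringSet(c(REF = "MKRLVN", cand = "MARLVN"))
  expect_identical(mapReferenceColumns(aln1, "REF", 1, 6), 1:6)

  # two leading gap columns shift every position by 2
  aln2 <- Biostrings::AAStringSet(c(REF = "--MKRLVN", cand = "QPMARLVN"))
  expect_identical(mapReferenceColumns(aln2, "REF", 1, 6), 3:8)

  # internal reference gaps are skipped in the residue count
  aln3 <- Biostrings::AAStringSet(c(REF = "MK--RLVN", cand = "MKQPRLVN"))
  expect_identical(mapReferenceColumns(aln3, "REF", 1, 6),
                   c(1L, 2L, 5L, 6L, 7L, 8L))

  # domain not starting at the first residue
  expect_identical(mapReferenceColumns(aln1, "REF", 3, 5), 3:5)

  # a trimmed-away column becomes NA and indices refer to the trimmed
  # alignment
  rows <- c(REF = "MKRLVN",
            setNames(rep("M-RLVN", 9), sprintf("c%d", 1:9)))
  tr <- trimAlignment(Biostrings::AAStringSet(rows), minOccupancy = 0.2)
  expect_identical(tr$keptColumns, c(1L, 3L, 4L, 5L, 6L))
  cols <- mapReferenceColumns(Biostrings::AAStringSet(rows), "REF", 1, 6,
                              trimReport = tr)
  expect_identical(cols, c(1L, NA_integer_, 2L, 3L, 4L, 5L))

  expect_error(mapReferenceColumns(aln1, "nope", 1, 6), "missing")
})

test_that("the binding rule table is exact over all residue combinations", {
  # identity alignment: 16 columns = domain positions 1..16
  mkRow <- function(r5, r9, r13, nBasic) {
    ch <- rep("S", 16)
    ch[5] <- r5; ch[9] <- r9; ch[12] <- "R"; ch[13] <- r13
    have <- sum(ch %in% c("R", "K", "H"))
    fillable <- setdiff(which(!ch %in% c("R", "K", "H")), c(5, 9, 12, 13))
    need <- nBasic - have
    stopifnot(need >= 0, need <= length(fillable))
    if (need > 0) ch[fillable[seq_len(need)]] <- "K"
    paste(ch, collapse = "")
  }
  cases <- expand.grid(r5 = c("H", "N"), r9 = c("E", "Q"),
                       r13 = c("R", "L"), nBasic = c(4L, 5L),
                       stringsAsFactors = FALSE)
  rows <- vapply(seq_len(nrow(cases)), function(i)
    mkRow(cases$r5[i], cases$r9[i], cases$r13[i], cases$nBasic[i]),
    character(1))
  names(rows) <- sprintf("case%02d", seq_len(nrow(cases)))
  aln <- Biostrings::AAStringSet(c(rows, REF = paste(rep("A", 16),
                                                     collapse = "")))
  out <- predictBinding(aln, 1:16, names(rows))
  for (i in seq_len(nrow(cases))) {
    # recount basic residues independently of the implementation
    nb <- sum(strsplit(rows[i], "")[[1]] %in% c("R", "K", "H"))
    expect_identical(out$n_basic[i], nb)
    expect_identical(nb, cases$nBasic[i])
    expect_identical(out$dna_binding[i], cases$nBasic[i] >= 5L,
                     info = paste("case", i))
    expect_identical(out$ebox_binding[i], cases$r9[i] == "E",
                     info = paste("case", i))  # R12 fixed in every row
    expect_identical(out$gbox_binding[i],
                     cases$r5[i] == "H" && cases$r9[i] == "E" &&
                       cases$r13[i] == "R", info = paste("case", i))
    expect_identical(out$res5[i], cases$r5[i])
    expect_identical(out$res9[i], cases$r9[i])
    expect_identical(out$res12[i], "R")
    expect_identical(out$res13[i], cases$r13[i])
  }
})

test_that("proline-rich basic regions can bind E-boxes but not DNA broadly", {
  # E at 9 and R at 12 (the lone basic residue) in a proline-rich region
  row <- "PPPPPSSSEPPRPPPP"
  aln <- Biostrings::AAStringSet(c(x = row))
  out <- predictBinding(aln, 1:16, "x")
  expect_false(out$dna_binding)
  expect_true(out$ebox_binding)
  expect_false(out$gbox_binding)
  expect_identical(out$n_basic, 1L)
})

test_that("an all-gap basic region is unevaluable with every call false", {
  aln <- Biostrings::AAStringSet(c(x = paste(rep("-", 16), collapse = "")))
  out <- predictBinding(aln, 1:16, "x")
  expect_false(out$evaluable)
  expect_false(any(out$dna_binding, out$ebox_binding, out$gbox_binding))
  expect_identical(out$res5, "-")
  expect_identical(out$res13, "-")
})

test_that("positions trimmed out of the alignment disable the affected rules", {
  cols <- c(1:4, NA_integer_, 6:16)  # position 5 unavailable
  row <- "RKRK-RRRERRRRRRR"
  aln <- Biostrings::AAStringSet(c(x = row))
  out <- predictBinding(aln, cols, "x")
  expect_identical(out$res5, "-")
  expect_false(out$gbox_binding)  # needs H at 5
  expect_true(out$dna_binding)    # count over the remaining columns
})

test_that("binding prediction in the pipeline matches the planted truth", {
  b <- testBundle()
  tp <- makeToyProteome(12, 0, seed = 84)
  all <- c(tp$seqs, b$baitSeqs)
  aln <- alignSequences(all)
  tr <- trimAlignment(aln)
  refDom <- detectDomains(b$baitSeqs["BAIT_A01"], b$domainHmm)
  cols <- mapReferenceColumns(aln, "BAIT_A01", refDom$env_start,
                              refDom$env_end, trimReport = tr)
  out <- predictBinding(tr$alignment, cols, names(tp$seqs))
  m <- merge(out, tp$truth, by.x = "candidate", by.y = "id")
  expect_identical(m$dna_binding.x, m$dna_binding.y)
  expect_identical(m$ebox_binding.x, m$ebox_binding.y)
  expect_identical(m$gbox_binding.x, m$gbox_binding.y)
  expect_identical(m$n_basic.x, m$n_basic.y)
})
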