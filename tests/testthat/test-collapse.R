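test_that("an isolated candidate forms a singleton group", {
  tr <- labeledTree("((C1:0.5,B1:0.5):0.5,(B2:0.5,B3:0.5):0.5);",
                    c(C1 = "candidate", B1 = "ingroup_bait",
                      B2 = "ingroup_bait", B3 = "ingroup_bait"))
  seqs <- Biostrings::AAStringSet(c(C1 = "MKRLV"))
  out <- collapseParalogs(tr, seqs)
  expect_identical(nrow(out), 1L)
  expect_identical(out$members, "C1")
  expect_identical(out$representative, "C1")
})

test_that("an isoform cherry collapses to its longest member", {
  # three isoforms in one tight clade, bait well outside
  tr <- labeledTree(
    "(((C1:0.01,C2:0.01):0.01,C3:0.02):0.40,(B1:0.10,B2:0.10):0.40);",
    c(C1 = "candidate", C2 = "candidate", C3 = "candidate",
      B1 = "ingroup_bait", B2 = "ingroup_bait"))
  seqs <- Biostrings::AAStringSet(c(
    C1 = paste(rep("A", 200), collapse = ""),
    C2 = paste(rep("A", 310), collapse = ""),
    C3 = paste(rep("A", 250), collapse = "")))
  out <- collapseParalogs(tr, seqs, cutoffFactor = 1)
  expect_identical(nrow(out), 1L)
  expect_identical(out$members, "C1,C2,C3")
  expect_identical(out$representative, "C2")  # 310 aa wins
  expect_identical(out$n_members, 3L)
})

test_that("the walk stops at the first bait even when candidates lie beyond", {
  # C2 is within distance of C1 but separated from it by bait B1
  tr <- labeledTree(
    "((C1:0.01,B1:0.01):0.01,(C2:0.01,B2:0.5):0.01);",
    c(C1 = "candidate", C2 = "candidate", B1 = "ingroup_bait",
      B2 = "ingroup_bait"))
  seqs <- Biostrings::AAStringSet(c(C1 = "MK", C2 = "MKR"))
  out <- collapseParalogs(tr, seqs, cutoffFactor = 50)
  # B1 is C1's nearest neighbour (edge distance 2): the walk stops at once
  expect_identical(out$members[out$seed == "C1"], "C1")
  expect_identical(nrow(out), 2L)
})

test_that("groups always partition the candidate set", {
  for (seed in 1:100) {
    lt <- randomLabeledTree(nCandidates = sample(2:8, 1),
                            nIngroup = sample(1:5, 1),
                            nOutgroup = sample(0:3, 1), seed = 1300 + seed)
    cands <- candidateLeaves(lt)
    widths <- setNames(sample(50:400, length(cands)), cands)
    seqs <- Biostrings::AAStringSet(vapply(widths, function(w)
      paste(rep("A", w), collapse = ""), character(1)))
    cf <- sample(c(0.5, 1, 2), 1)
    out <- collapseParalogs(lt, seqs, cutoffFactor = cf)
    members <- unlist(strsplit(out$members, ","))
    expect_setequal(members, cands)                 # coverage
    expect_identical(length(members), length(cands))  # disjointness
    expect_true(all(out$representative %in% cands))
    for (i in seq_len(nrow(out))) {
      mem <- strsplit(out$members[i], ",")[[1]]
      expect_true(out$representative[i] %in% mem)
      expect_identical(max(widths[mem]),
                       unname(widths[out$representative[i]]))
    }
  }
})

test_that("grouping matches the brute-force oracle on random trees", {
  for (seed in 1:60) {
    lt <- randomLabeledTree(nCandidates = sample(3:10, 1),
                            nIngroup = sample(1:6, 1),
                            nOutgroup = sample(0:4, 1), seed = 1500 + seed)
    cands <- candidateLeaves(lt)
    widths <- setNames(sample(50:400, length(cands)), cands)
    seqs <- Biostrings::AAStringSet(vapply(widths, function(w)
      paste(rep("A", w), collapse = ""), character(1)))
    cf <- sample(c(0.5, 1, 1.5), 1)
    got <- collapseParalogs(lt, seqs, cutoffFactor = cf)
    want <- oracleCollapse(lt, widths, cutoffFactor = cf)
    expect_identical(nrow(got), length(want))
    for (i in seq_len(nrow(got))) {
      w <- want[[got$seed[i]]]
      expect_identical(strsplit(got$members[i], ",")[[1]], w$members)
      expect_identical(got$representative[i], w$representative)
    }
  }
})

test_that("a larger cutoff never increases the number of groups", {
  for (seed in 1:20) {
    lt <- randomLabeledTree(nCandidates = 8, nIngroup = 3, nOutgroup = 2,
                            seed = 1700 + seed)
    cands <- candidateLeaves(lt)
    seqs <- Biostrings::AAStringSet(setNames(
      rep(paste(rep("A", 100), collapse = ""), length(cands)), cands))
    counts <- vapply(c(0.25, 0.5, 1, 2, 4), function(cf)
      nrow(collapseParalogs(lt, seqs, cutoffFactor = cf)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("representative trees conserve leaves and decorate reference labels", {
  b <- testBundle()
  tp <- makeToyProteome(4, 0, seed = 95)
  reps <- tp$seqs
  lt <- representativeTree(reps, b$baitSeqs, treeTool = "nj")
  expect_setequal(names(leafRoles(lt)),
                  c(names(reps), names(b$baitSeqs)))
  # decorated labels carry alt name and subfamily
  dec <- representativeTree(reps, b$baitSeqs,
                            referenceTable = b$reference, treeTool = "nj")
  lbl <- names(leafRoles(dec))
  expect_true("BAIT_A02|SynA-2|S-A" %in% lbl)
  expect_true(all(names(reps) %in% lbl))  # candidates undecorated
})

test_that("collapsing representatives again at the same cutoff is stable", {
  # separable fixture: two tight candidate clades far apart with baits
  tr <- labeledTree(paste0(
    "(((C1:0.01,C2:0.01):0.01,B1:0.30):0.50,",
    "((C3:0.01,C4:0.01):0.01,B2:0.30):0.50);"),
    c(C1 = "candidate", C2 = "candidate", C3 = "candidate",
      C4 = "candidate", B1 = "ingroup_bait", B2 = "ingroup_bait"))
  seqs <- Biostrings::AAStringSet(c(C1 = "MK", C2 = "MKR", C3 = "MKRL",
                                    C4 = "MK"))
  g1 <- collapseParalogs(tr, seqs, cutoffFactor = 0.5)
  expect_identical(nrow(g1), 2L)
  expect_setequal(g1$representative, c("C2", "C3"))
  # a second pass on the representatives alone finds only singletons
  reps <- g1$representative
  keep <- c(reps, "B1", "B2")
  sub <- ape::keep.tip(treePhylo(tr), keep)
  lt2 <- labeledTree(sub, leafRoles(tr)[keep])
  g2 <- collapseParalogs(lt2, seqs[reps], cutoffFactor = 0.5)
  expect_identical(nrow(g2), length(reps))
  expect_true(all(g2$n_members == 1L))
})
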