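# A candidate inside a bracket of 3 bait leaves, as in the schematic
# classification scenarios: the 3 nearest baits vote and the ingroup
# fraction decides.
fig5Tree <- function(third = c("out", "in")) {
  third <- match.arg(third)
  roles <- c(C1 = "candidate", I1 = "ingroup_bait", I2 = "ingroup_bait",
             N3 = if (third == "in") "ingroup_bait" else "outgroup_bait",
             O1 = "outgroup_bait", O2 = "outgroup_bait",
             I9 = "ingroup_bait")
  # C1's nearest baits by edge count: I1 (2 edges), I2 (3), N3 (4);
  # O1/O2/I9 sit farther on the other side
  labeledTree(
    "((((C1:0.10,I1:0.10):0.05,I2:0.10):0.05,N3:0.10):0.20,((O1:0.10,O2:0.10):0.10,I9:0.30):0.20);",
    roles)
}

test_that("a candidate with 2 ingroup baits among its 3 neighbours is ingroup", {
  res <- classifyLeaf(fig5Tree("out"), "C1")
  expect_identical(res$n_in, 2L)
  expect_identical(res$n_out, 1L)
  expect_equal(res$score, 2 / 3)
  expect_identical(res$label, "ingroup")
  expect_identical(res$selected_neighbours, "I1,I2,N3")
})

test_that("a candidate with 1 ingroup bait among its 3 neighbours is outgroup", {
  roles <- c(C1 = "candidate", O1 = "outgroup_bait", O2 = "outgroup_bait",
             I1 = "ingroup_bait", I2 = "ingroup_bait", I3 = "ingroup_bait")
  tr <- labeledTree(
    "((((C1:0.10,O1:0.10):0.05,O2:0.10):0.05,I1:0.10):0.20,(I2:0.10,I3:0.10):0.20);",
    roles)
  res <- classifyLeaf(tr, "C1")
  expect_identical(res$n_in, 1L)
  expect_identical(res$n_out, 2L)
  expect_equal(res$score, 1 / 3)
  expect_identical(res$label, "outgroup")
})

test_that("a score exactly at the minimum is outgroup (strictly greater wins)", {
  # 4 neighbours, 2 in / 2 out -> score 0.5 -> outgroup
  roles <- c(C1 = "candidate", I1 = "ingroup_bait", I2 = "ingroup_bait",
             O1 = "outgroup_bait", O2 = "outgroup_bait")
  tr <- labeledTree("((C1:0.1,(I1:0.1,O1:0.1):0.1):0.1,(I2:0.1,O2:0.1):0.1);",
                    roles)
  res <- classifyLeaf(tr, "C1", classifyParams(nNeighbours = 4L))
  expect_identical(res$n_in + res$n_out, 4L)
  expect_equal(res$score, 0.5)
  expect_identical(res$label, "outgroup")
})

test_that("candidate leaves never vote in a neighbourhood", {
  roles <- c(C1 = "candidate", C2 = "candidate", C3 = "candidate",
             I1 = "ingroup_bait", O1 = "outgroup_bait", O2 = "outgroup_bait")
  # C1's closest leaves are candidates C2/C3; baits vote regardless
  tr <- labeledTree(
    "(((C1:0.05,C2:0.05):0.05,C3:0.05):0.1,((O1:0.1,O2:0.1):0.1,I1:0.1):0.1);",
    roles)
  res <- classifyLeaf(tr, "C1")
  sel <- strsplit(res$selected_neighbours, ",")[[1]]
  expect_length(intersect(sel, c("C2", "C3")), 0L)
  expect_identical(res$n_in + res$n_out, 3L)
})

test_that("baits beyond the outlier cutoff are excluded; none left flags no_baits", {
  roles <- c(C1 = "candidate", C2 = "candidate", C3 = "candidate",
             C4 = "candidate", C5 = "candidate", C6 = "candidate",
             I1 = "ingroup_bait")
  # the only bait sits on a branch far beyond 5x MNTD of the candidate star
  tr <- labeledTree(
    "(C1:0.01,C2:0.01,C3:0.01,C4:0.01,C5:0.01,C6:0.01,I1:50);", roles)
  res <- classifyLeaf(tr, "C1")
  expect_identical(res$flag, "no_baits")
  expect_identical(res$label, "outgroup")
  expect_equal(res$score, 0)
  expect_identical(res$excluded_outliers, "I1")
})

test_that("classification matches the brute-force oracle on random trees", {
  set.seed(123)
  nTrials <- 300
  for (trial in seq_len(nTrials)) {
    lt <- randomLabeledTree(nCandidates = sample(1:6, 1),
                            nIngroup = sample(2:8, 1),
                            nOutgroup = sample(1:6, 1),
                            seed = 5000 + trial)
    k <- sample(1:5, 1)
    of <- sample(c(0.5, 1, 2, 5), 1)
    cands <- candidateLeaves(lt)
    cd <- cands[sample(length(cands), 1)]
    got <- classifyLeaf(lt, cd, classifyParams(nNeighbours = k,
                                               outlierFactor = of))
    want <- oracleClassifyLeaf(lt, cd, nNeighbours = k, outlierFactor = of)
    expect_identical(got$n_in, want$n_in, info = paste("trial", trial))
    expect_identical(got$n_out, want$n_out, info = paste("trial", trial))
    expect_equal(got$score, want$score, info = paste("trial", trial))
    expect_identical(got$label, want$label, info = paste("trial", trial))
  }
})

test_that("labels are invariant to leaf input order (total tie-break order)", {
  # deliberate exact ties: all branch lengths equal
  nwk1 <- "((C1:1,(I1:1,I2:1):1):1,((O1:1,O2:1):1,(I3:1,O3:1):1):1);"
  nwk2 <- "(((O3:1,I3:1):1,(O2:1,O1:1):1):1,(C1:1,(I2:1,I1:1):1):1);"
  roles <- c(C1 = "candidate", I1 = "ingroup_bait", I2 = "ingroup_bait",
             I3 = "ingroup_bait", O1 = "outgroup_bait", O2 = "outgroup_bait",
             O3 = "outgroup_bait")
  r1 <- classifyLeaf(labeledTree(nwk1, roles), "C1")
  r2 <- classifyLeaf(labeledTree(nwk2, roles[sample(7)]), "C1")
  expect_identical(r1$label, r2$label)
  expect_identical(r1$selected_neighbours, r2$selected_neighbours)
  expect_equal(r1$score, r2$score)
})

test_that("requiring the domain vetoes candidates without it", {
  tr <- fig5Tree("in")
  params <- classifyParams(requireDomain = TRUE)
  with_dom <- classifyLeaf(tr, "C1", params, domainPresent = TRUE)
  without <- classifyLeaf(tr, "C1", params, domainPresent = FALSE)
  expect_identical(with_dom$label, "ingroup")
  expect_identical(without$label, "outgroup")
  expect_equal(without$score, with_dom$score)  # score unaffected, label vetoed
})

test_that("a classification pass separates planted family members from noise", {
  b <- testBundle()
  tp <- makeToyProteome(6, 0, seed = 61)
  # planted-partition negatives: candidates that are copies of outgroup
  # members, so they sit squarely inside the outgroup clade
  decoyish <- b$outgroupSeqs[1:4]
  names(decoyish) <- paste0("OGC_", names(decoyish))
  cand <- c(tp$seqs, decoyish)
  pass <- classifyPass(cand, b$baitSeqs, b$outgroupSeqs,
                       domainHmm = b$domainHmm, treeTool = "nj")
  expect_setequal(pass$ingroup, names(tp$seqs))
  expect_setequal(pass$outgroup, names(decoyish))
  expect_identical(nrow(pass$results), length(cand))
})

test_that("binning splits candidates while keeping every bin anchored", {
  b <- testBundle()
  tp <- makeToyProteome(7, 0, seed = 71)
  params <- classifyParams(parallelThreshold = 6L, binSize = 5L)
  pass <- classifyPass(tp$seqs, b$baitSeqs, b$outgroupSeqs,
                       params = params, treeTool = "nj")
  expect_identical(sort(unique(pass$results$bin)), c(1L, 2L))
  expect_identical(sum(pass$results$bin == 1L), 5L)
  expect_identical(sum(pass$results$bin == 2L), 2L)
  # every bin tree carries the complete bait + outgroup anchor set
  for (lt in pass$trees) {
    expect_true(all(names(b$baitSeqs) %in% baitLeaves(lt)))
    expect_true(all(names(b$outgroupSeqs) %in% baitLeaves(lt)))
  }
  # at the threshold exactly, a single tree is built ("over" triggers)
  tp6 <- makeToyProteome(6, 0, seed = 72)
  params6 <- classifyParams(parallelThreshold = 6L, binSize = 5L)
  pass6 <- classifyPass(tp6$seqs, b$baitSeqs, b$outgroupSeqs,
                        params = params6, treeTool = "nj")
  expect_length(pass6$trees, 1L)
})

test_that("two passes only ever shrink the candidate set", {
  b <- testBundle()
  set.seed(202)
  for (i in 1:12) {
    tp <- makeToyProteome(sample(3:6, 1), 0, seed = 300 + i)
    noise <- makeToyProteome(0, sample(2:4, 1), seed = 400 + i)$seqs
    cand <- c(tp$seqs, noise)
    cls <- twoPassClassify(cand, b$baitSeqs, b$outgroupSeqs,
                           treeTool = "nj")
    expect_true(all(cls$final %in% cls$pass1$ingroup))
    expect_true(all(cls$pass1$ingroup %in% names(cand)))
  }
})

test_that("candidates identical to baits survive both passes", {
  b <- testBundle()
  copies <- b$baitSeqs[c("BAIT_A02", "BAIT_B02", "BAIT_C02", "BAIT_A05")]
  names(copies) <- paste0("COPY_", names(copies))
  cls <- twoPassClassify(copies, b$baitSeqs, b$outgroupSeqs, treeTool = "nj")
  expect_setequal(cls$final, names(copies))
})
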