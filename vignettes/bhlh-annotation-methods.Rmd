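---
title: "Phylogenetic identification and annotation of bHLH transcription factors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic identification and annotation of bHLH transcription factors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model behind `bHLHfinder`, the parameters
that matter, the synthetic data the tests run on, and the design choices
made where several reasonable implementations existed. It states no
empirical number that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem and the model

bHLH transcription factors share a short (~60 aa) domain: a basic,
DNA-contacting N-terminal region (roughly the first 10–19 residues)
followed by a helix-loop-helix dimerization region. Two features make
family annotation by plain similarity search unreliable. First, the
domain is variable enough that diverged members fall under practical
BLAST cutoffs. Second, several related protein groups carry
helix-loop-helix-like regions without being bHLHs, so a permissive
search drags in false positives.

`bHLHfinder` treats membership as a *phylogenetic* question. Candidates
from a deliberately permissive search are placed in a tree together with
two curated anchor sets: known bHLHs (ingroup baits) and bHLH-similar
non-bHLHs (outgroup baits). A candidate's label comes from the
composition of its nearest bait neighbours:

* bait leaves are ranked by **edge count** (number of edges on the leaf
  path — robust to branch-length noise), with ties broken by patristic
  distance and then identifier, so the ranking is a total order and the
  result cannot depend on input order;
* leaves farther than `outlierFactor` × MNTD (mean nearest taxon
  distance: the mean over leaves of each leaf's distance to its nearest
  neighbour) are discarded first — long, isolated branches carry no
  reliable neighbourhood information;
* the first `nNeighbours` surviving baits vote; with
  $n_\mathrm{in}$ and $n_\mathrm{out}$ votes the score is
  $s = n_\mathrm{in}/(n_\mathrm{in}+n_\mathrm{out})$ and the candidate
  is ingroup iff $s > \texttt{minScore}$ (strictly: an exactly balanced
  neighbourhood is *not* evidence of membership).

Classification runs twice. The first tree contains every initial
candidate, including non-bHLHs that distort the alignment; the second
tree is built only from first-pass survivors and is therefore cleaner.
The final set is the second pass's ingroup, so
final ⊆ pass-1 ingroup ⊆ initial candidates always holds (this chain is
property-tested).

Candidate leaves never vote, only baits do — otherwise a cluster of
false positives could vouch for itself.

## Parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `minBitScore` | 60 | bits | candidate search floor; diverged true members sit just above it |
| `minSimilarity` | 40 | % identity | with the bit-score floor, excludes spurious short matches |
| `minAlignLength` | 80 | aa | spans the ~60-aa domain plus flanks; no published value exists for this cutoff, so it is explicit and configurable |
| `nNeighbours` | 3 | leaves | smallest odd neighbourhood that cannot tie at 0.5 |
| `minScore` | 0.5 | fraction | ingroup requires a strict majority |
| `outlierFactor` | 5 | × MNTD | removes long-branch leaves; value is a package choice, configurable |
| `minBaitsInSelection` | 1 | leaves | a candidate with no bait near it is unclassifiable, hence outgroup |
| `parallelThreshold` / `binSize` | 600 / 500 | candidates | alignment cost grows quickly beyond ~600 sequences; bins keep full anchor sets |
| occupancy cutoff | 10 % | per column | columns below it are alignment noise; *exactly* 10 % is kept (strict "less than" removes) |
| `minBasic` | 5 | residues | conventional cutoff separating DNA-binding bHLHs from atypical HLHs; exactly 5 passes |
| basic-region span | positions 1–16 | domain coords | fixed width inside the reported 10–19 aa range, anchored on the reference bHLH; configurable |
| `cutoffFactor` | 1 | × MNTD | isoform clades are tighter than the typical nearest-neighbour distance |

The "minimum number of baits" rule is implemented as a *joint* minimum
on ingroup + outgroup baits in the selection; per-role minima would
declare candidates unclassifiable in perfectly clean regions of the tree
that simply contain no outgroup.

Binding rules: DNA binding ⇔ `n_basic ≥ minBasic` counted over the
basic-region columns with basic = {R, K, H} (histidine is
physiologically protonatable and prominent at position 5 of G-box
binders, so it is counted; the set is configurable); E-box ⇔ E at
position 9 **and** R at position 12 — the structurally motivated pair,
with the residue at 12 computed and reported alongside 5/9/13; G-box ⇔
H5 ∧ E9 ∧ R13. The three calls are computed independently (no implied
hierarchy is enforced), and a candidate whose basic region is entirely
gapped in the alignment is flagged unevaluable with every call `FALSE`
rather than guessed.

## External tools and numerical choices

Alignment (MAFFT default, Muscle5 supported), tree building (FastTree2
with the WAG model, RAxML-NG with LG+G) and all HMM work (HMMER 3) run
behind small adapters that write the input, check the exit status and
never modify sequence content (checksummed in tests). Two in-package
numerical components exist:

* **`nj` trees** — pairwise p-distances with pairwise gap deletion
  (disjoint rows get distance 1), `ape::njs()`, negative branch lengths
  clamped to 0, 3-leaf stars solved in closed form. Deterministic and
  fast; used throughout the test suite and the acceptance benchmark.
* **HMM inclusion** — a hit is accepted when its full-sequence E-value
  and its per-domain independent E-value are both ≤ 0.01, HMMER's
  default inclusion cutoffs; no score threshold is tuned.

All tree metrics are computed on the *unrooted* topology: tree tools
root arbitrarily, and a degree-2 root would inflate edge counts by one
for paths crossing it. Zero-length branches are legal and still count
one edge. Ties anywhere (neighbour ranking, ortholog choice,
representative choice) resolve by the documented chains ending in
lexicographic identifier, making every output reproducible under
permutation of the input.

Identifier hygiene: whitespace and the Newick/HMMER-breaking characters
`; : , ( ) [ ] ' "` are replaced by `_` before any tool runs, with
collisions resolved by numeric suffixes; the sanitization is idempotent
and the mapping is bijective, so all final tables carry the user's
original headers.

## What the synthetic data emulate — and what they do not

The fixture generator builds a self-consistent toy system:

* a synthetic 60-aa domain consensus with the bHLH architecture
  (16-residue basic region carrying H5/E9/R12/R13, then
  helix-loop-helix), in three "subfamilies" that differ by six fixed
  substitutions, and three binding profiles (G-box, E-box-only, and an
  atypical proline-rich region with zero basic residues);
* per-subfamily protein *scaffolds* (N-flank, linker, C-tail) shared by
  all members of a subfamily, so family members are full-length
  homologs, as real gene-family members are — point mutations at 8 %
  per site, never touching the basic region, plus 0–15 aa end
  truncations for isoform-like length variation;
* baits (10 per subfamily at 3 % divergence; one exact-consensus anchor
  playing the reference-bHLH role for binding-position mapping), an
  outgroup with its own scaffold and a 45 %-mutated domain copy
  (alignable but phylogenetically clearly outside), a consistent
  reference table, and HMMs built with `hmmbuild` from mutated consensus
  copies;
* decoys: uniform-random sequences of matching length.

Everything is a pure function of its arguments and seed (byte-identical
reruns, property-tested).

What this does **not** emulate: insertions/deletions inside the domain,
rate heterogeneity across sites, compositional bias of real proteomes,
paralogs at intermediate divergence, or baits with incomplete domains.
A perfect score on the planted benchmark therefore demonstrates that the
machinery is correct — search finds exactly the planted domains, the
tree separates the planted partition, annotation transfers along it —
not that real proteomes will be error-free. On real data, residual
errors with this kind of strategy concentrate in long-branch outliers
and atypical members, which is why the `requireDomain` veto and the
outlier exclusion exist as options.

Problem sizes in the shipped tests and acceptance script (12–50 planted
members, 30 baits, 10 outgroup, trees up to ~140 leaves; oracle checks
on hundreds of random trees ≤ 32 leaves) were chosen so the whole suite
exercises every step, including the external tools, in a few minutes on
one CPU. The benchmark uses the built-in `nj` tree so its result does
not depend on which external tree tool happens to be installed. Because
the synthetic proteins share homology along their full (~130–170 aa)
length, the default 80-aa alignment-length threshold behaves on the toy
system just as it does on real proteins.

## Known limitations

* Subfamily assignment uses the nearest reference leaf as a proxy for
  clade membership; it is exact for monophyletic subfamilies but can
  mislabel representatives that attach between subfamilies (the
  acceptance run reports this accuracy rather than asserting it).
* The isoform-collapsing walk applies the distance cutoff seed-to-member
  (not between consecutive members) and stops at the first bait; very
  elongated isoform clades can therefore split into several groups.
* Coding-sequence input is translated in frame 1 only; ORF finding is
  out of scope.
* The classification emits no statistical support values; confidence
  lives in the two-pass agreement and the tree itself.
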