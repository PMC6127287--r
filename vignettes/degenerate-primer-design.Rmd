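---
title: "Designing and evaluating degenerate group-specific primers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating degenerate group-specific primers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degeprimer)
```

## Motivation and model

Group-specific amplicon sequencing concentrates reads on a taxonomic
group whose members are rare in a complex community. The design problem
has three coupled parts, and `degeprimer` implements each as a module
with an explicit contract:

1. find sites conserved across *all* group members (allowing degenerate
   bases where the group varies),
2. pair sites so the product is long enough to separate species, and
3. verify, in silico, both specificity (targets amplify, outgroups do
   not) and resolution (few species pairs exceed a high identity
   threshold over the amplified fragment).

The motivating application is a lactic-acid-bacteria (LAB) panel across
seven genera; the packaged `lab_primers.tsv` fixture carries that
published six-pair panel (L1–L6, with the L5 pair
`GCTCAGGAYGAACGCYGG` / `CACCGCTACACATGRADTTC` and its ~750 bp product as
the reference geometry used throughout the defaults).

## The IUPAC algebra

Every sequence operation reduces to a 4-bit encoding of the 15 IUPAC
codes (A=1, C=2, G=4, T=8; e.g. Y = C|T = 10). Two letters *match* iff
their masks intersect. This gives degenerate primers their semantics for
free: a Y position matches C and T templates at zero mismatch cost. The
brute-force counterpart — expanding a degenerate oligo into its concrete
sequences (capped at 1024) — is kept as an exported primitive because it
is the natural oracle against which the fast bit-mask matcher is tested.

## Alignment and consensus

The built-in aligner is a textbook progressive scheme sized for desk
use: a k-mer (k = 6) distance matrix feeds a UPGMA guide tree
(`hclust(method = "average")`), and groups merge by affine-gap global
profile–profile alignment (compiled DP). Scores default to match +1,
mismatch −1, gap open −4, gap extend −1, with a gap run of length L
costing `gap_open + L*gap_extend` — deliberately the same convention as
`Biostrings::pairwiseAlignment`, which the identity/distance code uses,
so both alignment routes agree. DP ties break in a fixed order
(diagonal, then gap-in-second), making alignments reproducible. Inputs
beyond a few hundred sequences should come pre-aligned through
`as_alignment()`; no attempt is made at iterative refinement or
structure-aware 16S alignment.

Column profiles count A/C/G/T/gap per column; degenerate letters in
input references contribute fractionally (1/|bases| to each of their
bases) rather than being discarded, so the A+C+G+T+gap total always
equals the row count. The *minimal degenerate consensus* of a column is
the smallest IUPAC code covering every base whose frequency among
non-gap observations reaches `min_fraction`. The default
`min_fraction = 0` is the strictest setting — every observed base must
be covered — which is exactly the "primer must match all targets"
requirement; raising it trades coverage for lower degeneracy. Columns
containing any gap are disqualified from primer windows outright.

## Design constraints

Defaults encode the published regime: primer length 17–24 nt, at most
2 degenerate positions, predicted product strictly greater than 400 bp,
and 100% target coverage at the locus with zero mismatches. Window
enumeration considers *every* length in [17, 24] rather than only
maximal conserved blocks, because primers of different lengths at one
site are legitimate alternatives (the packaged panel itself has 17, 18,
19 and 23 nt variants at one site). Identical (sequence, orientation)
candidates from overlapping windows are merged keeping the widest
window. Product sizes are measured on a designated ungapped reference
row (default: the first), matching how product sizes are reported
against real templates; position labels (`41f`, `771r`) are the 1-based
start on that reference. The melting-temperature column is a screening
estimate only (Wallace rule below 14 nt, else 64.9 + 41·(GC−16.4)/N,
degenerate positions averaged over expansions); annealing temperatures
are an empirical matter.

## In-silico PCR

Matching is ungapped: a primer site is a placement with at most
`max_mismatches` incompatible positions and *zero* within the
3′-terminal anchor. The anchor length defaults to 3 — the source
procedure says only that 3′-mismatched alignments were deleted, without
a count, and three terminal bases is the common in-silico PCR
convention; it is config-exposed. General screening uses
`max_mismatches = 2`; the discriminability workflow uses the strict
policy (0 mismatches outside degeneracies, anchor 3). No indels are
allowed in primer placements, matching how primers are aligned to
reference loci in practice. All hits per template are reported (16S can
contain near-repeats); downstream consumers use the flagged primary hit
(fewest mismatches, then shortest product, then leftmost).

## Discriminability

Pairwise identity = identical columns / aligned columns of a global
affine-gap alignment, with terminal-gap columns excluded so partial
inserts are not penalized for length; internal gaps count as
differences. Distances are 1−identity (p-distance, the default),
JC69 (−¾ ln(1−4p/3)) or K2P from transition/transversion proportions;
the distance software used in the original workflow does not pin down a
model, and all three are cheap to offer. Saturated corrections (log
argument ≤ 0) are set to a configurable maximum with a warning.

"Difficult to distinguish" is operationalized as the fraction of all
unordered pairs with identity ≥ threshold (default 98%). Whether
same-species pairs belong in the denominator is genuinely ambiguous, so
a `species` mapping optionally restricts the denominator to
between-species pairs; the default counts all pairs.

Trees are Saitou–Nei neighbor joining, implemented in the package with a
deterministic tie-break (lexicographically lowest label pair among
minimal-Q candidates) so results are reproducible; `ape::nj` serves as
an independent cross-check in the test suite, and additive matrices are
recovered exactly (Robinson–Foulds 0, path lengths reproduced).
Negative NJ branch lengths are clamped to zero with a warning, the
standard practice. No bootstrap, likelihood or visualization — newick
out, `ape` in.

## Survey summaries

Depth standardization subsamples every read set, without replacement and
seeded, to the smallest sample (`depth = "auto"`). OTUs are exact-string
dereplication — the natural reading of a 100% pairwise identity
threshold, and unambiguous; no denoising or chimera removal is
attempted. Taxonomy is best-match identity against a user-supplied
labeled reference with a 0.97 default threshold (the conventional
species-level proxy; recorded in outputs), ties going to the first
reference in file order with a flag. Shannon uses natural logarithms
(base 2 is a flag). Rarefaction points are means over seeded
without-replacement replicates; the closed-form hypergeometric
expectation Σᵢ(1 − C(N−nᵢ, d)/C(N, d)) is the oracle the tests compare
against. Display rounding of percentages copies the survey-table
style — integers at ≥ 1%, one decimal below 1% — while raw values are
always kept.

## The synthetic clade: what it emulates, and what it does not

`generate_clade()` builds targets as
`flank + forward site + insert + revcomp(reverse site) + flank` with the
packaged panel's best-pair geometry by default (18 + 712 + 20 = 750 bp).
Choices that matter:

* **Degenerate positions are realized per target** (uniform over the
  allowed bases), so consensus calling must re-derive the degeneracies —
  a fixture that realized every Y as C would let a non-degenerate
  designer pass.
* **Insert and flank positions substitute independently** at
  `divergence = 0.10` per target relative to a common root (typical
  pairwise differences near 19%, a realistic inter-species scale for a
  variable 16S region); substitution-only evolution keeps the true
  alignment gap-free and the construction ground truth exact.
* **Engineered near-duplicates** (`n_close_pairs`, 0.5% divergence
  within a pair) plant a known count of pairs above the 98% identity
  threshold, giving the indistinguishable-pair statistic an exact
  expected value.
* **Non-targets are rejected** until they share no 17-mer with either
  site on either strand and carry no ≤2-mismatch near-site, so
  zero-amplification assertions are structural rather than
  probabilistic.

The generator does *not* emulate indel evolution, rate heterogeneity,
intragenomic 16S copy variation, chimeras or platform error profiles.
Passing tests therefore demonstrate the correctness of the algorithms
under clean substitution-only conditions, not robustness of primer
design against real-world alignment ambiguity.

Read sets (`generate_reads()`) draw labeled reads from inserts (or full
sequences, emulating a universal primer) under a stated composition at
depth 2551 by default — the depth-standardization size used in the
worked examples — with optional per-base error and a small decoy pool
backing the off-target fraction.

## Problem sizes and numerical choices

The test suite and acceptance script run the pipeline at sizes chosen to
exercise every code path while completing comfortably on one CPU: the
end-to-end clade uses 20 targets + 5 non-targets at the full 750 bp
geometry; the discriminability clade uses 50 inserts (1225 pairs) with 5
engineered close pairs; matcher-vs-oracle equivalence uses 1,000 random
templates; NJ recovery uses 100 random trees of 5–12 leaves; rarefaction
uses 200 replicates against the closed form (with a 10⁻³ absolute floor
on the 3-SE band, since near-exhaustive depths are almost deterministic
and their SE estimate collapses). Degenerate expansion is capped at
1024-fold; expansion-oracle equivalence is asserted up to 64-fold.
Coordinates are 0-based half-open internally; position labels in reports
are 1-based, following the field's primer-naming convention. `U` is
silently normalized to `T` (16S data are sometimes RNA-coded); any other
non-IUPAC character is a hard error, because silently accepting junk
hides corruption. `.` in alignments becomes `-`.

## Known limitations

* The aligner is desk-scale; thousands of sequences need an external
  alignment.
* No thermodynamic screening (dimers, hairpins, extension efficiency) —
  the Tm column ranks, nothing more.
* Taxonomy is single-best-hit against one reference set; no
  lowest-common-ancestor logic across databases.
* The indistinguishable-pair statistic depends on the reference set
  supplied; numbers computed on different reference collections are not
  comparable.
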