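---
title: "Methods: conserved-domain discovery with DomainScout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved-domain discovery with DomainScout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(DomainScout)
```

This vignette documents the models, parameters, numerical choices and known
limitations behind each stage of the domain-discovery workflow. It states
no empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## 1. Conservation scoring and domain delimitation

**Model.** The per-column conservation score is the AMAS-style property
count: with the ten Taylor/Zvelebil residue classes (shipped verbatim as
`conservationProperties()`), a column scores one point for every class
whose membership status — all residues in, or all residues out — is uniform
down the column. Identical columns score 10. Gaps and `X` are treated as
residues belonging to no class: they break the conservation of any class
present in the column while still allowing "conserved absence" to count.
This penalizes gapped columns without leaving scores undefined.

A consequence of the published class table worth knowing: four residue
pairs (A/G, C/T, I/L, W/Y) have identical membership vectors, so a column
containing only such a pair still scores 10. This is a property of the
classification itself, not an implementation artifact, and the tests
assert it explicitly.

**Smoothing.** The profile is smoothed with a centered moving average,
window 10 columns, step 1, truncated at the alignment edges (for even
windows the extra position is taken to the right). Window and step are
parameters; window 1 is the identity.

**Delimitation.** Domains are maximal runs of *smoothed* score strictly
above the threshold (default 4, in score units on the 0–10 scale), after
merging runs separated by at most `mergeGap` columns (default 10 — one
smoothing window) and discarding runs shorter than `minLen` columns
(default 25, well below any plausible domain length but above smoothing
noise). Known well-conserved anchor residues lying within `mergeGap` of a
boundary extend the segment minimally — this mirrors the common practice of
pinning boundaries to conserved residues rather than to the raw threshold
crossing. The threshold applies to the smoothed curve because that is the
curve boundaries are read from in practice; with near-threshold flanks the
detected boundaries are soft by up to about one window, which is why the
boundary-recovery tests assert ±10 columns.

**Identity statistics.** Percent identity of a pair counts positions where
both rows are non-gap (the most common convention; the alternative
alignment-length denominator deliberately not used because it conflates
truncation with divergence). Pairs with no comparable positions are
excluded from means.

## 2. Profile HMM

**Topology.** A Plan7-like node model: match states `M1..MM` with
per-node `M→M/I/D`, `I→M/I`, `D→M/D` transitions, local entry `B→Mk`
uniform over match states, local exit `Mk→E` with probability
`1/(M−k+1)` (which makes the end node approximately uniform a priori and
forces exit at the last node), and flanking background states before and
after the model with self-loop probability 350/351 (mean flank length
roughly one protein length; flank emissions cancel in the odds score, so
the loop only contributes a mild length penalty). The model is
**HMMER-like but not bit-compatible with HMMER**: no Dirichlet mixture
priors, no multi-hit mode, no heuristic filters.

**Parameterization.** Columns with more than 50% gaps become insert
columns. Match emissions mix observed (Henikoff position-weighted)
frequencies `f` with substitution-matrix conditionals
`g_a = Σ_b P(a|b) f_b` as `(1−α)f + αg`, `α = 20/(20+n_eff)` with
`n_eff` the number of seed sequences; the conditionals come from the
half-bit BLOSUM62 or BLOSUM90 log-odds matrices (embedded) under BLOSUM62
marginal frequencies. A plus-one Laplace mode exists for unit tests.
Transition counts are Laplace-smoothed; inserts following a delete are
skipped (Plan7 has no `D→I`/`I→D`).

**Scoring.** Viterbi and Forward run in log2-odds space against an i.i.d.
background null (compiled kernels). `X` residues emit with odds 1. Viterbi
reports the envelope (target span of the first and last match state on the
optimal path) and the per-state match positions used to grow iterative
seeds. Forward ≥ Viterbi always; on models with ≤ 6 states the Forward
score is checked against an exhaustive enumeration over all legal state
paths.

**E-values.** Decoy sequences drawn from the background are Viterbi-scored
and a Gumbel is fitted by maximum likelihood;
`E(s) = N(1 − exp(−exp(−λ(s−μ))))` for a database of `N` sequences.
HMMER's λ conventions are deliberately not reproduced; what is validated
instead is parameter recovery on synthetic Gumbel samples (λ within 15% at
n = 2000) and recall/precision on planted-domain benchmarks. Default 200
decoys (minimum 50); the benchmark suites use 100 to keep runtimes short
without affecting the conclusions.

**Iterative search.** Each round rebuilds the model from the current seed,
searches, and adds the match-aligned envelopes of all hits found so far to
the seed; iteration stops at `maxIter` (default 3) or at the first round
that adds no new sequence. Hit lists are cumulative — a target keeps its
discovery iteration and the list is monotone non-shrinking — and the decoy
seed is fixed across rounds so E-values are comparable. Reach extends
across rounds through two mechanisms: emission sharpening as `n_eff`
grows, and bridging through intermediate homologs. The two-tier test uses
a chain-structured family (seed → intermediate tier → remote tier) because
with a long domain a simple two-level divergence is either detected
immediately or never; the chain is the regime where iteration demonstrably
matters, and the test asserts aggregate remote-recall gain over seeds
rather than a per-seed count.

**Tie-breaking.** Hits sort by (E-value asc, target id asc); Viterbi ties
resolve toward the smaller start coordinate.

## 3. Architecture census

Overlapping hits on one protein are resolved greedily by descending score
(ties: earlier start, then name); a candidate overlapping a kept hit by
more than `max(10 residues, 20% of the shorter hit)` is dropped, smaller
overlaps are trimmed so the result is strictly non-overlapping. Greedy
selection by score is not a globally optimal weighted interval scheduling —
for mutually overlapping hit sets (the case that matters for nested domain
calls) it coincides with the brute-force optimum, which the tests verify.

Census percentages are computed over proteins that contain the target
domain (single-copy fraction, target-only fraction, co-occurrence); the
same fractions over all proteins in the table are reported alongside for
tables that include target-free proteins. Percentages are kept exact
internally and rounded only for display.

## 4. Sequence-side trees

Design choice made openly: maximum-likelihood inference with model
selection and aLRT supports is *not* reimplemented at desk scale. The
pipeline substitutes distance methods — p or Kimura-corrected protein
distances (`d = −ln(1 − p − 0.2p²)`, refusing saturated pairs at
p ≥ 0.85), Saitou–Nei neighbor joining (via ape, negative branch lengths
clamped to zero with a message) and column bootstrap (saturated replicates
skipped and counted). NJ recovers additive matrices exactly, which the
tests exercise on random 4–8 taxon trees; an externally computed newick
tree can be supplied to downstream steps instead.

Redundancy removal is the greedy identity clustering rule (descending
ungapped length, join the first representative at ≥ 95% identity) computed
exactly on shared alignment columns rather than with k-mer screens — exact
and deterministic at desk scale. Column trimming uses a single gap-fraction
rule (keep columns with ≤ 20% gaps) in place of heuristic ensembles; the
kept/total counts are always reported so users can compare against other
trimmers. All three filters are idempotent.

## 5. Structure-side trees

Residue correspondence between two C-alpha traces comes from a sequence
MSA (columns where both rows are non-gap), not from a multiple structure
alignment: for families of models built on a shared template the two are
near-identical, and sequence pairing keeps the stage deterministic and
dependency-free. Mismatches between a structure's residues and its MSA row
are hard errors with position and residue reported.

Kabsch superposition is the SVD solution with determinant correction
(proper rotations only); degenerate (collinear) point sets are refused.
The structural distance is `100·RMSD/n_aligned`, and each pair is computed
once so the matrix is symmetric by construction.

The Fitch–Margoliash tree minimizes `Σ (d−p)²/d^P` (default power 2;
power 0 gives unweighted least squares) by stepwise taxon addition in
input order followed by nearest-neighbor-interchange local search, with
branch lengths from non-negative weighted least squares (active-set
clamping, ridge 1e-10 for rank safety). The search strategy is validated
against an exhaustive 15-topology oracle at n = 5 and against exact
recovery (E ≤ 1e-10) on additive matrices at n = 4–7. Off-diagonal zero
distances are replaced by 1e-8 with a warning because the weight `1/d²`
is undefined at zero.

## 6. Synthetic data: what it emulates and what it does not

All generators are pure functions of (parameters, seed); golden-value
tests pin one output per generator, and the caller's RNG state is restored.

* `simulateDomainFamily()` plants one conserved domain (i.i.d. per-site
  substitutions from a consensus, replacement drawn from the background)
  between unrelated background flanks. Under a uniform background the
  expected pairwise identity inside the domain is
  `(1−p)² + p(2−p)/20` — the exact form, including the cross term in
  which exactly one sequence is substituted. Defaults: n = 14 sequences,
  193-residue domain, `p_sub` = 0.17, chosen once so the expected domain
  identity is 70.4%, matching the ~70% conservation level typical of a
  within-kingdom seed family of a strongly conserved domain.
* `simulateReferenceFamily()` emulates the full-length seed protein: 550
  residues, conserved blocks at 116–182 (a GRAM-like putative
  lipid-binding block) and 257–449 (the 193-residue core domain) at
  `p_sub` 0.17, the remainder at 0.30 — giving ~60% expected full-length
  identity (comfortably above a 55% retrieval floor) while keeping flank
  conservation below the delimitation threshold.
* `defaultArchitectureCatalogue()` fixes six architectures whose masses
  encode, among target-containing proteins, 85.8% single-copy, 21.9%
  target-only and 70.3% GRAM co-occurrence; `simulateArchitectureSet()`
  draws from it multinomially and lays domains out with random linkers.
* `evolveOnTree()` evolves sites independently along a tree
  (Jukes–Cantor-like on 20 letters) for tree-recovery tests;
  `additiveMatrix()` provides exact path-length matrices as oracles.
* `simulateStructures()` builds group-specific C-alpha traces (3.8 Å
  steps, bounded turning angle) and perturbs members with i.i.d. Gaussian
  noise plus a random rigid motion; expected member-to-member RMSD scales
  with σ√6 (≈ 1.2 Å at σ = 0.5), which the tests check as a band.

**Not emulated:** realistic indel processes (flanks are unrelated rather
than gapped homologs), site-rate heterogeneity, compositional bias,
taxonomic structure, and genuine fold variability in structures. Passing
tests therefore demonstrate correctness of the algorithms under their
stated statistical models, not performance on real proteomes — in
particular real-sequence conservation profiles are burstier than the
i.i.d. emulation, and real structural families violate the shared-residue
assumption of the trivial pairing MSA.

## 7. Problem sizes and reproducibility

The test and acceptance workloads use the study-scale defaults: 14-member
seed families, 193-residue domains, databases of 20 planted targets plus
80 background sequences, 452-protein census sets, 341-column trimming
instances with 125 low-gap columns, two structure groups of eight at
σ = 0.5 Å, and 10–20 replicates for stochastic rates. The pipeline fans a
single global seed out to per-stage seeds by stable hashing of stage
names, so toggling one stage never shifts another's random stream; reruns
with the same configuration are bit-identical (no timestamps are written).

## 8. Known limitations

* No bit-compatibility with HMMER scores, file formats or E-values; no
  DNA models; one envelope per target (no multi-domain splitting).
* The conservation score is the 0–10 property-count variant; other
  implementations rescale it, so the >4 threshold is exposed as a
  parameter rather than hard-coded.
* Greedy overlap resolution and greedy redundancy clustering are
  order-deterministic heuristics, not global optima (see §3, §4).
* The Fitch–Margoliash NNI search can in principle stop in a local
  optimum for n beyond the exhaustively validated range.
* Delimitation boundaries erode by a few columns at domain edges
  (smoothing) and soften further when flank conservation approaches the
  threshold.
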