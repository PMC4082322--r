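# DomainScout

Discovery and characterization of novel conserved protein domains from a
seed family of homologous sequences.

Many protein families carry uncharacterized regions that are strongly
conserved but escape existing domain annotations — the tell-tale signature
of an unrecognized domain. DomainScout packages the complete desk-scale
workflow for turning such a signature into a characterized domain family:

1. **Conservation profiling and delimitation.** Per-column conservation of a
   seed-family alignment is scored as the number of physicochemical residue
   property classes (the ten Taylor/Zvelebil classes: hydrophobic, polar,
   small, proline, tiny, aliphatic, aromatic, positive, negative, charged)
   whose membership is uniform down the column, giving an integer score
   *c ∈ \[0, 10\]*. A centered 10-column moving average is thresholded
   (*c* > 4) to delimit candidate domains, reported in both alignment and
   reference-residue coordinates.
2. **Profile-HMM expansion.** A profile hidden Markov model (match, insert
   and delete states; local alignment with uniform entry) is built from the
   delimited ungapped domain alignment with substitution-matrix
   pseudocounts (BLOSUM62/BLOSUM90) and Henikoff position-based weights.
   Sequences are scored in log2-odds bits by Viterbi and Forward dynamic
   programming; E-values come from a maximum-likelihood Gumbel fit to
   background decoy scores, *E(s) = N(1 − exp(−exp(−λ(s − μ))))*. A
   jackhmmer-style iterative search (default: E ≤ 1e-10, 3 iterations)
   grows the seed with the match-aligned envelopes of all hits.
3. **Architecture census.** Per-protein domain hits are resolved into
   ordered, non-overlapping architectures (`GRAM-VASt`,
   `C2-VASt-C2-GRAM-VASt`, ...) and summarized: copy-number histogram of
   the target domain, fraction with a single copy, fraction with the target
   as the only domain, and co-occurrence percentages of partner domains.
4. **Sequence-side phylogeny.** Completeness filtering, greedy redundancy
   removal, gap-fraction column trimming, p / Kimura protein distances
   (*d = −ln(1 − p − 0.2p²)*), neighbor-joining trees and column-bootstrap
   supports.
5. **Structure-side phylogeny.** Kabsch least-squares superposition of
   C-alpha traces paired through a sequence alignment, the
   length-normalized structural distance *100·RMSD/n<sub>aligned</sub>*, and
   Fitch–Margoliash weighted least-squares trees minimizing
   *E = Σ (d<sub>ij</sub> − p<sub>ij</sub>)² / d<sub>ij</sub><sup>P</sup>* with
   power *P = 2* (stepwise addition + nearest-neighbor interchanges,
   non-negative branch lengths).

Seeded generators (`simulateDomainFamily()`, `simulateReferenceFamily()`,
`simulateArchitectureSet()`, `evolveOnTree()`, `simulateStructures()`)
produce ground-truthed synthetic inputs for every stage, so the entire
workflow is testable without database downloads.

## Worked example

Delimit the conserved core of a simulated 14-member homolog family (a
550-residue protein with conserved blocks planted at residues 116–182 and
257–449), then census a 452-protein architecture set:

```r
library(DomainScout)

fam  <- simulateReferenceFamily(n = 14, seed = 1)
prof <- smoothProfile(conservationProfile(fam$alignment), window = 10)
delimitDomains(prof, fam$alignment, fam$reference_id,
               threshold = 4, minLen = 25, mergeGap = 10)
#>   start_col end_col start_res end_res length_res
#> 1        37      76        37      76         40
#> 2       117     189       117     189         73
#> 3       249     448       249     448        200

meanPairwiseIdentity(fam$alignment, c(257, 449))    # 69.4
minIdentityToReference(fam$alignment, fam$reference_id)  # 56.5

census <- simulateArchitectureSet(n = 452, seed = 1)
architectureSummary(census$hits, "VASt")
#> Architecture census for target 'VASt'
#>   452 proteins contain the target (of 452 in table)
#>   single copy: 87.4%   target-only: 20.1%
#>   co-occurring domains:
#>     GRAM       71.0%
#>     C2         10.0%
#>     ...
```

The second delimited segment is the planted 67-residue block (116–182); the
third tracks the planted 193-residue domain (257–449) — boundaries are soft
by a few columns because the moving average mixes flanking columns in. The
census reproduces the catalogue the set was drawn from (85.8% single copy,
21.9% target-only, 70.3% GRAM co-occurrence) up to binomial sampling noise
at *n* = 452.

`runPipeline()` chains all stages from one (YAML-able) configuration,
writes every artifact (profiles, segments, serialized HMM, hit tables,
census, PHYLIP matrices, newick trees) into a run directory, and is
bit-reproducible for a fixed seed.

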