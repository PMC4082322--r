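Package: DomainScout
Title: Discovery and Characterization of Conserved Protein Domains from Seed Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering a novel protein domain starting from a seed
    family of homologous sequences: physicochemical-property conservation
    profiling of a multiple alignment with moving-average smoothing and
    threshold-based domain delimitation; profile hidden Markov model
    construction, relative-entropy logos, Viterbi/Forward scoring with
    decoy-calibrated E-values and jackhmmer-style iterative database search;
    a census of multi-domain architectures of the retrieved proteins; a
    sequence-side tree pipeline (redundancy and completeness filtering,
    gap-fraction column trimming, protein distances, neighbor joining with
    bootstrap); and a structure-side tree pipeline (C-alpha Kabsch
    superposition, length-normalized RMSD distances, Fitch-Margoliash
    weighted least-squares trees). Seeded generators of ground-truthed
    synthetic families, architectures, tree-evolved alignments and C-alpha
    structures make every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    bio3d,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
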