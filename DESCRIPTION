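Package: phylocap
Title: Target-Capture Phylogenomics: Simulation, Filtering, Informativeness,
    Gene and Species Trees, Bait Selection, and Index Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for target-capture (Hyb-Seq) phylogenomic
    workflows. Simulates multispecies-coalescent data sets (species trees,
    gene trees with incomplete lineage sorting, GTR+Gamma alignments,
    VCF-style variant tables, gene metadata); applies site filters to
    variant tables and extracts full-sequence per-region alignments;
    profiles per-gene phylogenetic informativeness from per-site
    substitution rates; estimates maximum-likelihood gene trees with
    nonparametric bootstrap support; builds partitioned supermatrices;
    infers quartet-based coalescent species trees with per-branch quartet
    support and local posterior probabilities; selects loci under a bait
    budget with an auditable multi-criterion filter and exon bait tiling;
    and designs balanced dual-index barcode sets with a minimum pairwise
    edit-distance guarantee.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
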