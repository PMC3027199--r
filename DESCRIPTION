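Package: mtlineage
Title: Human mtDNA Haplogroup Phylogeography: Variant Scoring, Motif
    Classification, Median-Joining Networks and Rho Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phylogeographic analysis of human mitochondrial DNA
    lineages. Scores control-region and coding-region variants against the
    revised Cambridge Reference Sequence (rCRS) in the standard position-based
    nomenclature (transitions as bare positions, transversion suffixes,
    "d"/"+" indels, "@" back mutations, R/Y heteroplasmies), applies the usual
    site masks (16519 and the C-stretch length regions), screens and assigns
    samples to haplogroups by diagnostic motif matching and near-matching
    against a nomenclature tree, condenses haplotypes and builds
    median-joining networks with quasi-median inference, and estimates
    coalescence ages with the rho statistic and its heuristic standard error
    under configurable molecular clocks, including the hypervariable segment I
    transition clock of 18,845 years per transition in positions 16090-16365.
    Includes seeded simulators for star and coalescent genealogies with
    Poisson mutation counts and for multi-population haplogroup surveys, plus
    haplogroup frequency tabulation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Biostrings, stats, utils, tools
Suggests: testthat (>= 3.0.0), igraph, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
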