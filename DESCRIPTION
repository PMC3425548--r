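Package: genefamdiv
Title: Diversity Analysis of Expressed Detoxification Multigene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of cloned coding-sequence sets from multigene families,
    built around the hepatic cytochrome P450 2B (CYP2B) subfamily of a wild
    herbivore. Validates and translates cloned open reading frames,
    dereplicates amino-acid variants by percent identity with gaps, builds
    distance trees, compares treatment-group expression on the tree with
    unweighted UniFrac permutation tests, quantifies selection with
    Nei-Gojobori synonymous/nonsynonymous counting (global dN/dS, codon
    z-test, per-site parsimony-based scans), fingerprints substrate
    recognition site residues and tests their substitution enrichment, and
    estimates relative gene copy number from qPCR quantification cycles.
    Includes a seeded gene-family simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phytools,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    picante,
    seqinr
Config/testthat/edition: 3
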