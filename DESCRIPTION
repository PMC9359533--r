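Package: overflapr
Title: Diversity and Template-Bias Analysis of Randomized Plasmid Peptide Libraries
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for amplicon sequencing of randomized plasmid
    peptide libraries built by whole-plasmid amplification. Provides anchored
    extraction of the randomized insert region from reads, global-alignment
    classification of template-biased (insufficiently randomized) products,
    peptide-level variant quantification, per-position amino acid composition
    compared with the uniform degenerate-codon (NNN) expectation, and library
    complexity estimation from cumulative probabilities of occurrence (CPO).
    Includes a synthetic amplicon read generator emulating biased and unbiased
    libraries with jackpot abundance skew, length aberrations and homopolymer
    sequencing errors, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
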