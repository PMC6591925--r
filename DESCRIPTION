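Package: bsbtools
Title: Bile Salt Biotransformation Gene Screening and Abundance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for bile salt biotransformation (BSB) genes in
    the human gut microbiome: calibrated homolog screening of BSB protein
    families (Smith-Waterman alignment with Karlin-Altschul significance,
    sensitivity-specificity threshold calibration, BSH/PVA discrimination,
    domain-architecture and annotation-concordance filters), protein sequence
    similarity networks with e-value threshold selection and connected
    component clustering, normalized metagenomic gene-abundance comparison
    between healthy and IBD groups with taxonomic stratification and
    nonparametric tests, and fecal bile-acid proportion analysis. Includes
    seeded synthetic-data generators emulating protein families, two-group
    cohort metagenomes and bile-acid metabolite tables so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
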