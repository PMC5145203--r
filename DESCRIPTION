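Package: gh2arch
Title: Domain Architectures and Catalytic-Domain Phylogenetics of Family 2
    Glycoside Hydrolases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies family 2 glycoside hydrolase (GH2) proteins into five
    domain-architecture (DA) types from Pfam-style envelope annotations,
    encodes architectures as repeat-aware binary vectors, extracts and
    clusters unannotated C-terminal extensions with BIG1-like module tagging,
    builds catalytic-domain (GH2C) phylogenies by neighbor joining with
    bootstrap supports and low-support condensation, reports concordance
    between DA types and tree clades, and profiles active-site residue
    conservation through alignment columns. Ships a synthetic-data generator
    that emulates a domain gain/fission evolutionary scenario so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    readr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
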