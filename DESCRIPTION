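Package: plastocmp
Title: Comparative Chloroplast Genome Analysis and Plastome Evolution
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of complete chloroplast
    (plastid) genomes among closely related taxa: detection of the
    quadripartite structure (large and small single-copy regions and the
    two inverted repeats), inverted-repeat reduction, anchor-based
    pairwise whole-plastome alignment with projection onto a common
    reference, variant calling and classification (SNP, multi-nucleotide
    variant, insertion, deletion) with transition/transversion typing,
    coding-effect prediction (synonymous, non-synonymous, frameshift with
    truncation length), clade-partitioned variant sets, event- and
    nucleotide-level distance matrices, maximum-parsimony phylogenetics
    (Fitch scoring, exhaustive and heuristic tree search with
    tree-bisection-reconnection branch swapping, consistency and
    retention indices, bootstrap support) with neighbor-joining
    cross-checks and outgroup rooting, and a quadripartite plastome
    evolution simulator that emits ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    readr,
    withr,
    optparse
Config/testthat/edition: 3
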