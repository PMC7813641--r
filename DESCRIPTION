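Package: mitosir
Title: Comparative Mitogenome Architecture: Inverted Repeats, Tandem
    Arrays and Gene-Order Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of small circular genomes,
    built around the repeat landscape of animal mitochondrial DNA. Detects
    maximal small inverted repeats (hairpin-forming palindromes) under a
    mismatch budget, classifies them into families by the six stem
    nucleotides adjacent to the loop, and tabulates per-genome and
    per-region statistics. Includes a seeded tandem-repeat detector with
    wraparound-alignment scoring, sliding-window GC profiles, dotplot
    matrices, p-distances with pairwise deletion, signed circular
    gene-order comparison with conserved-section merging and breakpoint
    distances, cohort summary statistics, and a synthetic annotated
    mitogenome generator that plants repeats and simulates
    inversion/translocation events along a phylogeny for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
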