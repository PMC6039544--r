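Package: phagecompare
Title: Comparative Genomics and Evolutionary Analysis of Phage Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for comparative analysis of bacteriophage genome
    collections: minimal ORF calling, protein family ("pham") assignment by
    single-linkage clustering over dual similarity thresholds, whole-genome
    dot plots, nucleotide-identity based genome clustering with singleton
    designation, CRISPR spacer (protospacer) searching for host-range
    inference, and a Nei-Gojobori piN/piS analysis of selection acting on
    gene families. Includes a synthetic genome and codon-family simulator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Biostrings,
    Rcpp,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    withr,
    mclust,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
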