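Package: srnapipe
Title: Small RNA Signature Pipeline: miRNA Hairpins, siRNA Clusters,
    Phased tasiRNAs and Repeat Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for characterizing endogenous plant small
    RNA populations from multi-tissue deep-sequencing libraries. Raw fixed-length
    adapter-ligated reads are trimmed, collapsed into unique signatures,
    abundance-thresholded and normalized to counts per million; signatures are
    mapped to a genome with bounded mismatches, annotated against a miRBase-like
    reference set and joined to gene models. Downstream stages validate miRNA
    loci by folding precursor windows into stem-loops with 5p/3p duplex geometry,
    discriminate broad double-stranded siRNA clusters from miRNA loci, detect
    trigger-miRNA cleavage sites and score 21-nucleotide phased tasiRNA
    production with an exact binomial register test, and profile transposable
    element families and rDNA-like tandem arrays by size class. A fully seeded
    synthetic-data generator plants hairpins, inverted repeats, a TAS-like
    phased locus, transposon families and tissue-differential library profiles
    so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
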