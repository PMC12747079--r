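Package: evekit
Title: Endogenous Viral Element Detection, Telomere Accounting, Read
    Recruitment and Survey Statistics for Protist Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational steps of a cultivation and
    genomics study of a heterotrophic freshwater cryptomonad: detection and
    classification of endogenous polinton-like viral elements in a nuclear
    genome from GC shifts, hallmark-gene anchors, terminal repeats and
    target-site duplications; telomere-based chromosome accounting and
    assembly statistics; covered-fraction-gated metagenomic read recruitment
    with metagenomic-island detection and fragment-based average nucleotide
    identity; CARD-FISH survey summaries with environmental correlation
    screens and in-situ doubling times; and growth-curve kinetics with
    collapse detection. A synthetic-data module generates ground-truth
    labelled genomes, alignments, survey tables and growth curves so the
    whole pipeline is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    withr
Config/testthat/edition: 3
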