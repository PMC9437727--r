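Package: miredit
Title: Allele-Aware Analysis of CRISPR/Cas9 Editing at miRNA Loci in Polyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, synthetically testable pipeline for evaluating
    dual-sgRNA CRISPR/Cas9 editing of microRNA loci in polyploid genomes such
    as tetraploid potato. Provides allele-aware genotyping of amplicon clones
    with natural-polymorphism masking, an ICE-style knock-out score from mixed
    Sanger trace deconvolution, a nearest-neighbour minimum-free-energy folding
    engine with MFEI and miRNA/miRNA* duplex features feeding an
    impaired-processing classifier, exclusion-based discovery of templated and
    non-templated miRNA variants from small-RNA reads, expectation-score
    target-retention screening, and relative standard-curve qPCR
    quantification. A seeded synthetic-data generator emulates every wet-lab
    input (tetraploid loci, edited amplicon clones, Sanger trace mixtures,
    small-RNA FASTQ, Cq tables) with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    Rcpp,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
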