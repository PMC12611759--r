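Package: ontarget
Title: Quantification of Large-Scale On-Target Genome-Editing Damage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies the large on-target lesions that standard
    short-read amplicon analysis misses after CRISPR-Cas9 editing. Implements
    four quantification workflows as pipe-friendly tibble-based tools:
    long-read amplicon filtering and read-length profiling of kilobase-scale
    deletions and HDR insertion alleles; anchor-pair plus Hamming-distance
    classification of short reads into HDR, wild-type and indel alleles;
    chromosome-segment expression-loss calling from edited versus unedited
    single-cell count matrices via residual relative expression; and Poisson
    copy-number quantification of droplet digital PCR assays. A synthetic-data
    module generates all four input types with known ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
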