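Package: pactr
Title: Poly(A)-Site Clustering and Comparative Alternative Polyadenylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Determines genome-wide poly(A) sites from mapped poly(A)-tag
    (PAT-seq) data and analyses alternative polyadenylation (APA) within and
    between species. Curates mapped poly(A) tags (poly(T)-prefix
    classification, mate-pair concordance, internal-priming removal against
    genomic oligo-A tracts), chains tags into poly(A)-site clusters (PACs),
    assigns PACs to genomic regions under merged and 3'-extended gene models,
    classifies antisense PACs around convergently transcribed gene pairs,
    computes position-by-position nucleotide composition profiles around
    cleavage sites, and runs cross-species conservation statistics (3'-UTR
    length comparison, ortholog correlation, randomization tests with
    chi-square statistics). Includes a synthetic-data generator with planted
    ground truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
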