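Package: spaceracq
Title: Dual-Locus CRISPR Spacer Acquisition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for CRISPR spacer acquisition in a dual-locus
    system pairing a DNA-targeting subtype II-C array with an RNA-targeting
    subtype VI-B array. Extracts newly acquired spacers from CRISPR-array
    amplicon reads with repeat-anchored parsing, collapses them into unique
    pools by greedy identity clustering, maps them hierarchically to phage
    and host genomes with an ungapped local aligner, infers guide-oriented
    spacer acquisition motifs (SAM/PAM), quantifies inter-locus spacer-pool
    sharing against Monte-Carlo sampling nulls, and tests mRNA-targeting
    bias with exact binomial machinery. A seeded synthetic-data generator
    produces genomes, acquisition events and error-bearing amplicon reads
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
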