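Package: clearclipr
Title: Chimeric CLIP Analysis of miRNA-Target Interactomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end toolkit for chimeric Argonaute CLIP (CLEAR-CLIP) sequencing
    data: read preprocessing (adapter/barcode handling, duplicate collapse),
    detection of miRNA-mRNA chimeric reads by word-seeded local alignment in
    transcript space, Argonaute binding-peak calling with spline summits and a
    Poisson background, clustering of chimeras into interactions with peak support,
    intermolecular nearest-neighbor duplex free-energy scoring against a shuffled
    null, seed-match density and k-mer motif register analysis, and temporal
    dynamics of interactions via self-organizing maps. A synthetic-data module
    generates libraries with planted ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    IRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    DESeq2,
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
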