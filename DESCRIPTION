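Package: ancar
Title: Ancestral Genome Reconstruction from Local Genome Rearrangement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for reconstructing contiguous ancestral regions (CARs)
    of polyploid plant genomes from signed genomic markers. Genomes are
    segmented into atomic markers from pairwise local alignments, syntenic
    blocks are discovered as reference-based approximate common intervals,
    scored and refined with a local double-cut-and-join (DCJ) similarity
    measure, and assembled into CARs via greedy weighted insertion into a
    PQ-tree. A polyploidy-aware simulator (whole-genome duplication and
    triplication followed by fractionation) provides ground truth for
    validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    igraph,
    Rcpp,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
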