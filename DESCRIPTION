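Package: anidot
Title: Alignment-Free Identity Heatmaps of Genomic Repeats via Modimizer
    Sketching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates average nucleotide identity (ANI) between all pairs
    of windows of one or two DNA sequences using fractional minhash
    ("modimizer") sketches and a bias-corrected containment index, and
    renders the result as self- or comparative identity heatmaps.
    A hierarchical multi-resolution sketch index supports zoom queries at
    geometrically increasing window sizes, and an adaptive sparsity rule
    keeps sketches informative inside low-complexity satellite arrays.
    Includes a deterministic synthetic-sequence generator (tandem
    higher-order repeat arrays with controlled divergence) so that every
    estimator can be validated against analytic expectations, plus BED
    export, matrix serialization and static square or triangular plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
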