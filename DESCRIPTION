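Package: acsk
Title: Alignment-Free Sequence Comparison with k-Mismatch Average Common
    Substrings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Alignment-free estimation of sequence dissimilarity from
    k-mismatch average common substrings (ACS_k).  Implements a linear-time
    forward/backward-extension heuristic for the per-position k-mismatch
    match-length statistics, together with the earlier kmacs and ALFRED-G
    greedy heuristics and a quadratic brute-force oracle for exact values on
    small inputs.  Matching statistics are computed from a generalized
    suffix array with LCP and range-minimum-query support.  Distances are
    assembled into symmetric matrices, trees are built by neighbor joining,
    and reconstructions are scored against reference trees with the
    Robinson-Foulds metric.  Includes a seeded sequence-evolution simulator
    and a command-line interface covering the full pipeline from FASTA input
    to Newick output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
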