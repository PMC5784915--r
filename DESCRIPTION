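Package: grmatrix
Title: Google Matrix and Reduced Google Matrix Analysis of Directed
    Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural analysis of directed biological
    networks (signaling and transcriptional regulatory networks) with
    Google-matrix methods.  Builds column-stochastic transition matrices
    with the standard dangling-node and damping-factor treatment, computes
    PageRank, CheiRank and 2DRank centralities, leading complex spectra
    with eigenvector localization (inverse participation ratio), and the
    analytic reduced Google matrix for a chosen protein subset, whose
    decomposition into direct, projector and hidden components scores
    indirect (hidden) causal relations between subset members.  Includes
    two-condition comparison of ranks and hidden interactions, seeded
    synthetic network generators with planted indirect pathways, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
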