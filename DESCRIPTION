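Package: polyepi
Title: Rational Design of Polyepitope T-Cell Antigens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing polyepitope T-cell antigens from a set of
    CTL epitopes. Optimizes TAP transport of each epitope by exhaustive search
    over up-to-three N-terminal flanking residues under an additive
    N1/N2/N3+C scoring model, selects inter-epitope spacers that create
    efficient proteasomal and immunoproteasomal cleavage sites while
    minimizing non-target junctional epitopes via an explicit ranking
    function, and orders the epitopes as a minimum-weight Hamiltonian path in
    a complete weighted digraph (exhaustive, greedy nearest-neighbour, or
    genetic-algorithm solvers). Also selects T-helper-rich antigen fragments
    joined through cathepsin-cleavable motifs and minimal epitope sets
    covering an HLA repertoire with redundancy. All scoring models (TAP
    matrix, cleavage rank tables, per-allele MHC position-specific scoring
    matrices) are pluggable parameter files; bundled generators emit clearly
    labelled synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
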