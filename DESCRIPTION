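Package: proteoprune
Title: Proteome Redundancy Minimization by Greedy Clustering and
    Dominating-Set Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies and removes highly redundant proteomes from
    collections of near-identical strain proteomes. Pairs of proteomes
    within a species group are compared by greedy asymmetric sequence
    clustering at a 90% identity cut-off, summarised into a
    length-weighted proteome similarity score, and assembled into a
    directed redundancy graph. The graph is reduced to a dominating set
    by iterative weakest-node elimination with rank recomputation,
    protected reference proteomes, and deterministic tie-breaking,
    yielding a minimal non-redundant proteome set with representative
    bookkeeping. Includes a deterministic synthetic strain-proteome
    generator with ground-truth redundancy labels and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
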