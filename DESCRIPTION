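Package: fluenet
Title: Semantic Network Analysis of Verbal Fluency Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and compares group-level semantic networks from
    category verbal-fluency lists. Raw responses are normalized against a
    deterministic lexicon, assembled into a binary participant-by-exemplar
    response matrix, converted to a cosine co-occurrence association matrix,
    and filtered to an unweighted planar graph with the Triangulated
    Maximally Filtered Graph (TMFG) algorithm. Groups are compared on
    average shortest path length, clustering coefficient and Louvain
    modularity through a case-wise bootstrap with unadjusted and
    covariate-adjusted models, plus a repeated-bootstrap consistency
    harness. Includes a synthetic cohort generator (stochastic block model
    world plus censored random walk retrieval) for calibration and power
    analysis without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
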