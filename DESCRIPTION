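Package: densemod
Title: Query-Seeded Enumeration of Dense, Enriched Modules in Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates all maximal gamma-dense, mu-enriched quasi-cliques of an
    undirected network with respect to a user-supplied query set of vertices
    (a "knowledge prior", e.g. phenotype-related proteins). A quasi-clique is
    gamma-dense when every member is adjacent to at least ceiling(gamma*(|S|-1))
    other members, and mu-enriched when at least mu*|S| members belong to the
    query set. The search is an agglomerative backtracking enumeration seeded
    from the query vertices, with distance-2 candidate restriction, degree- and
    enrichment-feasibility pruning, and a hierarchical bitmap registry of
    discovered modules for early backtracking. Includes readers for plain and
    STRING-style edge lists, an R-MAT synthetic graph generator with planted
    modules, an exhaustive reference enumerator for validation, and a benchmark
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
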