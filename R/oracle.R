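# Exhaustive reference enumerator.  Deliberately naive: every non-empty
# vertex subset is tested against the density and enrichment predicates and
# maximality is decided by comparing all surviving sets pairwise (feasibility
# is not anti-monotone in the subset order, so single-vertex extension checks
# would be wrong).  This is the correctness anchor for the backtracking
# search, its pruning rules and the bitmap registries.

#' Exhaustively enumerate maximal dense, enriched modules (small graphs)
#'
#' Scans all `2^n - 1` non-empty vertex subsets, keeps those of size at
#' least `params$min_size` that are gamma-dense and mu-enriched, and removes
#' every kept set that is a strict subset of another kept set.  Refuses
#' graphs with more than 22 vertices.
#'
#' Output order matches [enumerate_dense()]: size descending, then
#' lexicographic by sorted member labels.
#'
#' @param graph A `dense_graph` with at most 22 vertices.
#' @param query Query vertex indices (non-empty).
#' @param params A [dense_params()] object.
#' @return A `dense_modules` object.
#' @export
brute_force_maximal <- function(graph, query, params = dense_params()) {
  graph <- as_dense_graph(graph)
  params <- as_dense_params(params)
  if (graph$n_vertices > 22L) {
    stop("brute_force_maximal refuses graphs with more than 22 vertices (",
         graph$n_vertices, " given)")
  }
  query <- sort(unique(as.integer(query)))
  if (length(query) == 0L) stop("query set must be non-empty")
  stopifnot(all(query >= 1L), all(query <= graph$n_vertices))
  em <- graph_edge_matrix(graph)
  mods <- cpp_brute_force(graph$n_vertices, em[, 1] - 1L, em[, 2] - 1L,
                          query - 1L,
                          params$gp, params$gq, params$gamma_strict,
                          params$mp, params$mq, params$min_size)
  new_dense_modules(mods, graph, query, params, index = "none")
}
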