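# The query-seeded backtracking enumerator and the search-state operations
# it is built from.  The hot path lives in C++ (src/dense.cpp); the R
# functions here expose the individual search-state operations for
# inspection and testing, and wrap the kernel with validation, global
# maximality filtering and deterministic ordering.

#' Candidate universe for a search seed
#'
#' All vertices at distance 1 or 2 from `v0` (excluding `v0` itself), in
#' ascending internal-index order.  Because any gamma-dense set with
#' gamma > 0.5 has pairwise distance at most 2, this is the complete
#' candidate universe for modules containing `v0`.
#'
#' @param graph A `dense_graph`.
#' @param v0 Seed vertex index.
#' @return Sorted integer vector of candidate vertices.
#' @export
initial_candidates <- function(graph, v0) {
  graph <- as_dense_graph(graph)
  stopifnot(length(v0) == 1L, v0 >= 1L, v0 <= graph$n_vertices)
  n1 <- graph$adj[[v0]]
  n2 <- unique(c(n1, unlist(graph$adj[n1], use.names = FALSE)))
  sort(setdiff(n2, v0))
}

# s_a / c_a for one vertex
count_in <- function(graph, v, set) sum(graph$adj[[v]] %in% set)

#' Can the current subgraph still grow into a dense module?
#'
#' Expansion-feasibility bound: `TRUE` iff for every `v` in `S`,
#' `s_a(v) + c_a(v) >= required_degree(gamma, |S| + c_a(v))`, where `s_a`
#' and `c_a` count the neighbours of `v` inside `S` and inside the candidate
#' set `C`.  When `FALSE`, no supergraph of `S` drawn from `C` can be
#' gamma-dense, so the search emits `S` (if `S` itself qualifies) and
#' backtracks.  With an empty `C` this reduces to [is_gamma_dense()].
#'
#' @param graph A `dense_graph`.
#' @param S Current subgraph vertex indices.
#' @param C Candidate vertex indices (disjoint from `S`).
#' @param gamma Density threshold.
#' @param strict See [dense_params()].
#' @return `TRUE` or `FALSE`.
#' @export
extension_feasible <- function(graph, S, C, gamma, strict = FALSE) {
  graph <- as_dense_graph(graph)
  stopifnot(length(S) > 0L, length(intersect(S, C)) == 0L)
  r <- rationalize(gamma)
  for (v in S) {
    ca <- count_in(graph, v, C)
    sa <- count_in(graph, v, S)
    if (sa + ca < rat_min_degree(r["p"], r["q"], length(S) + ca - 1, strict))
      return(FALSE)
  }
  TRUE
}

#' Remove candidates that can never join a dense extension
#'
#' Degree-feasibility pruning: a candidate `v` survives only if
#' `s_a(v) + c_a(v) >= gamma * (|S| + c_a(v))` (exact rational comparison).
#' Removals lower the `c_a` counts of the remaining candidates, so the rule
#' is re-applied until a fixed point.
#'
#' @inheritParams extension_feasible
#' @return The pruned candidate vector (original order preserved).
#' @export
prune_candidates_density <- function(graph, S, C, gamma, strict = FALSE) {
  graph <- as_dense_graph(graph)
  stopifnot(length(S) > 0L, length(intersect(S, C)) == 0L)
  r <- rationalize(gamma)
  repeat {
    keep <- vapply(C, function(v) {
      ca <- count_in(graph, v, C)  # v is never its own neighbour
      sa <- count_in(graph, v, S)
      sa + ca >= rat_min_degree(r["p"], r["q"], length(S) + ca, strict)
    }, TRUE)
    if (all(keep)) return(C)
    C <- C[keep]
  }
}

#' Enrichment feasibility of a search branch
#'
#' The branch can still produce a mu-enriched module only if
#' `|S /\ Q| + |C /\ Q| >= mu * (|S| + |C /\ Q|)`: the most enriched
#' reachable extension adds exactly the query members of `C`.  In addition,
#' any non-query candidate whose inclusion would force a permanent violation
#' of that bound is removed.
#'
#' @inheritParams extension_feasible
#' @param query Query vertex indices.
#' @param mu Enrichment threshold in (0, 1].
#' @return A list with `feasible` (logical) and `candidates` (the pruned
#'   candidate vector).
#' @export
prune_enrichment <- function(graph, S, C, query, mu) {
  graph <- as_dense_graph(graph)
  stopifnot(length(S) > 0L, length(intersect(S, C)) == 0L)
  r <- rationalize(mu)
  sq <- sum(S %in% query)
  cq <- sum(C %in% query)
  feasible <- (sq + cq) * r["q"] >= r["p"] * (length(S) + cq)
  if (feasible) {
    # adding a non-query vertex leaves sq and cq unchanged but grows |S|
    drop <- !(C %in% query) &
      (sq + cq) * r["q"] < r["p"] * (length(S) + 1 + cq)
    C <- C[!drop]
  }
  list(feasible = unname(feasible), candidates = C)
}

index_kind_code <- function(index) {
  match(match.arg(index, c("none", "flat", "hierarchical")),
        c("none", "flat", "hierarchical")) - 1L
}

new_dense_modules <- function(modules, graph, query, params, nodes = NA_real_,
                              index = NA_character_) {
  labels <- graph$labels
  if (length(modules)) {
    key <- vapply(modules, function(m) paste(sort(labels[m]), collapse = ","),
                  "")
    ord <- order(-lengths(modules), key)
    modules <- lapply(modules[ord], function(m) sort(as.integer(m)))
  }
  structure(modules,
            n_query = vapply(modules, function(m) sum(m %in% query), 1L),
            params = params, nodes = nodes, index = index,
            class = "dense_modules")
}

#' @export
print.dense_modules <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("dense_modules: %d maximal module(s), gamma = %g%s, mu = %g\n",
              length(x), p$gamma, if (p$gamma_strict) "+" else "", p$mu))
  if (length(x)) {
    cat("  sizes: ", paste(sort(unique(lengths(x))), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.dense_modules <- function(x, row.names = NULL, optional = FALSE,
                                        graph, query, ...) {
  module_summary(x, graph, query)
}

assert_modules_sound <- function(modules, graph, query, params) {
  p <- params
  for (m in modules) {
    s <- length(m)
    need <- rat_min_degree(p$gp, p$gq, s - 1, p$gamma_strict)
    degs <- vapply(m, function(v) sum(graph$adj[[v]] %in% m), 1L)
    nq <- sum(m %in% query)
    if (s < p$min_size || any(degs < need) || nq * p$mq < p$mp * s) {
      stop("internal error: an emitted module violates the density or ",
           "enrichment constraint")
    }
  }
  invisible(TRUE)
}

#' Enumerate all maximal dense, enriched modules
#'
#' Finds every maximal vertex set that is gamma-dense (each member adjacent
#' to at least `ceiling(gamma * (|S| - 1))` other members), mu-enriched
#' (at least `mu * |S|` members in `query`) and of size at least
#' `params$min_size`.  The search is seeded from each query vertex in turn,
#' restricted to the seed's distance-2 neighbourhood, and pruned by the
#' expansion-feasibility, candidate-degree and enrichment-feasibility rules;
#' a bitmap registry of discovered modules cuts branches whose closure is
#' already covered.  A final maximality sweep guarantees the returned
#' collection is exactly the set of maximal modules, mutually incomparable
#' under inclusion.  Output is deterministic: modules are ordered by size
#' descending, then lexicographically by sorted member labels.
#'
#' @param graph A `dense_graph`.
#' @param query Query vertex indices (non-empty).
#' @param params A [dense_params()] object.
#' @param index Module registry backing the duplicate/covered-branch checks:
#'   `"hierarchical"` (default), `"flat"`, or `"none"` (no registry; results
#'   are identical, only runtime differs).
#' @param prune Which pruning rules to apply (all by default): `"extension"`
#'   (stop expanding when no dense supergraph is reachable), `"degree"`
#'   (drop infeasible candidates), `"enrichment"` (enrichment bound).
#'   Disabling rules never changes the result, only the runtime.
#' @return A `dense_modules` object: a list of sorted vertex-index vectors
#'   with per-module query counts in `attr(, "n_query")`.
#' @examples
#' g <- graph_from_edges(c("a", "a", "a", "b", "b", "c"),
#'                       c("b", "c", "d", "c", "d", "d"))  # K4
#' enumerate_dense(g, query = 1, dense_params(0.75, 0.001))
#' @export
enumerate_dense <- function(graph, query, params = dense_params(),
                            index = c("hierarchical", "flat", "none"),
                            prune = c("extension", "degree", "enrichment")) {
  graph <- as_dense_graph(graph)
  params <- as_dense_params(params)
  index <- match.arg(index)
  if (length(prune)) {
    prune <- match.arg(prune, c("extension", "degree", "enrichment"),
                       several.ok = TRUE)
  }
  query <- sort(unique(as.integer(query)))
  if (length(query) == 0L) stop("query set must be non-empty")
  stopifnot(all(query >= 1L), all(query <= graph$n_vertices))

  em <- graph_edge_matrix(graph)
  res <- cpp_enumerate(graph$n_vertices, em[, 1] - 1L, em[, 2] - 1L,
                       query - 1L,
                       params$gp, params$gq, params$gamma_strict,
                       params$mp, params$mq, params$min_size,
                       "extension" %in% prune,
                       "degree" %in% prune,
                       "enrichment" %in% prune,
                       index_kind_code(index))
  mods <- res$modules
  keep <- cpp_maximality_filter(mods)
  mods <- mods[keep]
  assert_modules_sound(mods, graph, query, params)
  new_dense_modules(mods, graph, query, params, nodes = res$nodes,
                    index = index)
}

#' Keep only inclusion-maximal modules
#'
#' Removes duplicates and every set that is a strict subset of another set
#' in the collection; the survivors are mutually incomparable.  Because
#' quasi-clique feasibility is not anti-monotone, this global sweep (not the
#' discovery-order registry) is the correctness mechanism for maximality.
#'
#' @param modules List of vertex-index vectors.
#' @param graph,query,params Optional; when all are supplied, each input set
#'   is first checked against the density/enrichment constraints (an error
#'   is raised on violation).
#' @return The filtered list, in the order first encountered.
#' @export
maximality_filter <- function(modules, graph = NULL, query = NULL,
                              params = NULL) {
  if (!is.null(graph) && !is.null(params)) {
    assert_input_feasible <- function() {
      graph <- as_dense_graph(graph)
      params <- as_dense_params(params)
      for (m in modules) {
        if (!is_gamma_dense(graph, m, params$gamma, params$gamma_strict) ||
            !is_mu_enriched(m, query, params$mu)) {
          stop("input set {", paste(m, collapse = ","),
               "} violates the density or enrichment constraint")
        }
      }
    }
    assert_input_feasible()
  }
  if (length(modules) == 0L) return(modules)
  modules[cpp_maximality_filter(modules)]
}
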