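# Shared fixtures: small deterministic graphs, random-graph builders and a
# naive pure-R enumerator that anchors the compiled reference oracle.

# graph on exactly n vertices (isolated ones kept), labels x1..xn
graph_n <- function(n, ei, ej) {
  densemod:::new_dense_graph(paste0("x", seq_len(n)), as.integer(ei),
                             as.integer(ej))
}

path_graph <- function(n) graph_n(n, seq_len(n - 1), 2:n)
cycle_graph <- function(n) graph_n(n, seq_len(n), c(2:n, 1L))
complete_graph <- function(n) {
  em <- t(utils::combn(n, 2))
  graph_n(n, em[, 1], em[, 2])
}

# Erdos-Renyi G(n, p), at least one edge guaranteed
er_graph <- function(n, p, seed) {
  densemod:::local_seed(seed, {
    up <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(up)) < p
    if (!any(keep)) keep[1] <- TRUE
    graph_n(n, up[keep, 1], up[keep, 2])
  })
}

canon <- function(mods) {
  sort(vapply(mods, function(m) paste(sort(m), collapse = ","), character(1)))
}

# the random-graph + parameter-grid suite shared by the equivalence tests:
# a mix of ER densities and small R-MAT graphs, all within the exhaustive
# oracle's reach
make_suite <- function(n_graphs = 200, seed = 2024) {
  densemod:::local_seed(seed, {
    lapply(seq_len(n_graphs), function(i) {
      kind <- i %% 5
      g <- if (kind == 4) {
        # R-MAT: heavy-tailed small graphs
        sc <- sample(3:4, 1)
        remove_isolated(rmat_graph(sc, sample(2:3, 1),
                                   seed = sample.int(1e6, 1)))
      } else if (kind == 3) {
        er_graph(sample(16:18, 1), 0.2, sample.int(1e6, 1))
      } else {
        er_graph(sample(8:15, 1), sample(c(0.2, 0.4, 0.6), 1),
                 sample.int(1e6, 1))
      }
      nq <- max(1L, stats::rbinom(1, g$n_vertices, 0.3))
      list(graph = g, query = sort(sample.int(g$n_vertices, nq)))
    })
  })
}

param_grid <- expand.grid(gamma = c(0.55, 0.75, 0.999),
                          mu = c(0.001, 0.5, 0.9))

# Pure-R exhaustive enumerator for tiny graphs (n <= 12): adjacency-matrix
# arithmetic, subset scan via combn, pairwise maximality filter.  Used only
# to anchor the compiled oracle.
naive_maximal <- function(g, q, gamma, mu, min_size = 2, strict = FALSE) {
  n <- g$n_vertices
  stopifnot(n <= 12)
  A <- matrix(FALSE, n, n)
  for (v in seq_len(n)) A[v, g$adj[[v]]] <- TRUE
  feasible <- list()
  for (k in seq(max(1, min_size), n)) {
    need <- required_degree(gamma, k, strict)
    for (S in utils::combn(n, k, simplify = FALSE)) {
      degs <- rowSums(A[S, S, drop = FALSE])
      if (all(degs >= need) && is_mu_enriched(S, q, mu))
        feasible[[length(feasible) + 1]] <- S
    }
  }
  keep <- vapply(seq_along(feasible), function(i) {
    !any(vapply(seq_along(feasible), function(j) {
      i != j && length(feasible[[j]]) > length(feasible[[i]]) &&
        all(feasible[[i]] %in% feasible[[j]])
    }, TRUE))
  }, TRUE)
  feasible[keep]
}
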