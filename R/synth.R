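# Synthetic data: R-MAT benchmark graphs and planted dense/enriched modules.
#
# All randomness flows through one explicit `seed` argument; the caller's
# global RNG state is saved and restored, so generation is reproducible and
# side-effect free.

local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Generate a recursive-matrix (R-MAT) random graph
#'
#' Draws each edge by recursively choosing one quadrant of the adjacency
#' matrix with probabilities `a` (top-left), `b` (top-right), `c`
#' (bottom-left), `d` (bottom-right), `scale` times, which yields the
#' skewed, power-law-like degree distributions typical of biological and
#' other scale-free networks.  Directed draws are symmetrized into unordered
#' pairs; self-loops and duplicate edges are rejected and redrawn until
#' exactly `edge_factor * 2^scale` distinct undirected edges exist, so the
#' mean degree is exactly `2 * edge_factor` (before isolated-vertex
#' removal).
#'
#' The defaults (`a = 0.45`, `b = 0.15`, `c = 0.15`, `d = 0.25`,
#' `edge_factor = 7`, i.e. average degree 14) are the standard benchmark
#' settings for this generator.
#'
#' @param scale Number of bisection levels; the graph has `2^scale` vertices.
#' @param edge_factor Edges per vertex (integer).
#' @param a,b,c,d Quadrant probabilities; must sum to 1.
#' @param seed Integer seed; same seed, same graph.
#' @return A `dense_graph` with labels `v1..v{2^scale}`.
#' @examples
#' g <- rmat_graph(scale = 5, edge_factor = 3, seed = 1)
#' g$n_edges  # exactly 96
#' @export
rmat_graph <- function(scale, edge_factor = 7, a = 0.45, b = 0.15, c = 0.15,
                       d = 0.25, seed) {
  stopifnot(scale >= 1, scale == floor(scale),
            edge_factor >= 1, edge_factor == floor(edge_factor))
  if (abs(a + b + c + d - 1) > 1e-12)
    stop("quadrant probabilities a + b + c + d must sum to 1")
  n <- 2^scale
  m <- edge_factor * n
  if (m > n * (n - 1) / 2)
    stop("requested ", m, " edges but a simple graph on ", n,
         " vertices has at most ", n * (n - 1) / 2)
  keys <- local_seed(seed, {
    acc <- numeric(0)
    pw <- 2^((scale - 1):0)
    while (length(acc) < m) {
      ndraw <- max(2L * (m - length(acc)), 64L)
      qd <- matrix(sample.int(4L, ndraw * scale, replace = TRUE,
                              prob = c(a, b, c, d)),
                   nrow = ndraw)
      # quadrants: 1 = (0,0), 2 = (0,1), 3 = (1,0), 4 = (1,1) as
      # (row bit, column bit) at each bisection level
      u <- as.vector((qd >= 3L) %*% pw)          # 0-based row index
      v <- as.vector((qd == 2L | qd == 4L) %*% pw)  # 0-based column index
      lo <- pmin(u, v)
      hi <- pmax(u, v)
      k <- (lo * n + hi)[lo != hi]
      k <- k[!duplicated(k)]
      acc <- c(acc, k[!(k %in% acc)])
    }
    acc[seq_len(m)]
  })
  new_dense_graph(paste0("v", seq_len(n)),
                  as.integer(keys %/% n) + 1L,
                  as.integer(keys %% n) + 1L)
}

#' Drop isolated vertices
#'
#' Returns the induced subgraph on vertices of degree at least 1.  Labels
#' are preserved; internal indices are re-assigned contiguously in the
#' original order; the edge set is unchanged.
#'
#' @param graph A `dense_graph`.
#' @return A `dense_graph` without isolated vertices.
#' @export
remove_isolated <- function(graph) {
  graph <- as_dense_graph(graph)
  keep <- lengths(graph$adj) > 0L
  if (all(keep)) return(graph)
  remap <- cumsum(keep)
  adj <- lapply(graph$adj[keep], function(x) remap[x])
  structure(
    list(labels = graph$labels[keep], adj = adj,
         n_vertices = sum(keep), n_edges = graph$n_edges),
    class = "dense_graph")
}

#' Plant a gamma-dense module into a graph
#'
#' Selects `size` vertices and adds within-set edges until every selected
#' vertex has at least `required_degree(gamma, size)` neighbours inside the
#' set, then marks `ceiling(query_fraction * size)` of the selected vertices
#' as query vertices.  Used as ground truth for recovery tests.
#'
#' @param graph A `dense_graph` to modify.
#' @param size Module size (>= 2; a single vertex cannot carry a density
#'   constraint).
#' @param gamma Density threshold the planted set must satisfy.
#' @param query_fraction Fraction of planted vertices marked as query
#'   vertices (0 gives an empty query addition).
#' @param seed Integer seed.
#' @param strict See [dense_params()].
#' @return A list with `graph` (the modified graph), `planted` (sorted
#'   planted vertex indices) and `query` (sorted query vertex indices,
#'   a subset of `planted`).
#' @export
plant_module <- function(graph, size, gamma, query_fraction, seed,
                         strict = FALSE) {
  graph <- as_dense_graph(graph)
  if (size < 2L) stop("planted module size must be at least 2")
  stopifnot(size <= graph$n_vertices,
            query_fraction >= 0, query_fraction <= 1)
  need <- required_degree(gamma, size, strict)
  local_seed(seed, {
    vs <- sort(sample.int(graph$n_vertices, size))
    adj <- graph$adj
    extra <- 0L
    repeat {
      ideg <- vapply(vs, function(v) sum(adj[[v]] %in% vs), 1L)
      if (all(ideg >= need)) break
      v <- vs[which(ideg < need)[1]]
      # connect to the in-set non-neighbour with the lowest internal degree
      cand <- setdiff(vs, c(v, adj[[v]]))
      u <- cand[which.min(ideg[match(cand, vs)])]
      adj[[v]] <- sort(c(adj[[v]], u))
      adj[[u]] <- sort(c(adj[[u]], v))
      extra <- extra + 1L
    }
    graph$adj <- adj
    graph$n_edges <- graph$n_edges + extra
    nq <- ceiling(query_fraction * size)
    list(graph = graph,
         planted = vs,
         query = sort(sample(vs, nq)))
  })
}
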