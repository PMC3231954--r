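# Benchmark harness: the three canonical parameter regimes on R-MAT graphs.

#' Canonical benchmark regimes
#'
#' The three parameter regimes used to exercise the enumerator:
#' \describe{
#'   \item{clique}{gamma = 0.999, mu = 0.001, query = every vertex - high
#'     density, low enrichment; modules are fully connected for sizes below
#'     1001.}
#'   \item{enriched}{gamma = 0.5 (boundary `>=`-variant: at least half),
#'     mu = 0.90, query = every 10th vertex - high enrichment, low density.}
#'   \item{dense}{gamma = 0.85, mu = 0.85, query = every 6th vertex -
#'     moderate enrichment and density.}
#' }
#'
#' @return A data frame with one row per regime: `regime`, `gamma`,
#'   `gamma_strict`, `mu`, `query_every`.
#' @export
benchmark_regimes <- function() {
  data.frame(
    regime = c("clique", "enriched", "dense"),
    gamma = c(0.999, 0.5, 0.85),
    gamma_strict = c(FALSE, FALSE, FALSE),
    mu = c(0.001, 0.90, 0.85),
    query_every = c(1L, 10L, 6L),
    stringsAsFactors = FALSE)
}

regime_config <- function(regime) {
  tab <- benchmark_regimes()
  row <- tab[tab$regime == regime, ]
  if (nrow(row) != 1L) {
    stop("unknown regime '", regime, "'; expected one of ",
         paste(tab$regime, collapse = ", "))
  }
  row
}

# query = every k-th vertex by internal index (1, 1+k, 1+2k, ...) after
# isolated-vertex removal
regime_query <- function(regime, n) {
  seq.int(1L, n, by = regime_config(regime)$query_every)
}

#' Run the R-MAT benchmark
#'
#' For each (regime, scale, seed): generate an R-MAT graph with
#' `edge_factor * 2^scale` edges, remove isolated vertices, take the
#' regime's query set (every k-th vertex by internal index), enumerate all
#' maximal dense enriched modules and record counts and timing.
#'
#' @param regimes Character vector of regime names (see
#'   [benchmark_regimes()]).
#' @param scales Integer vector of R-MAT scales (vertices = `2^scale`).
#' @param seeds Integer vector of generation seeds.
#' @param edge_factor Edges per vertex (default 7, i.e. mean degree 14).
#' @param min_size Minimum module size (default 2).
#' @param index Registry backing (see [enumerate_dense()]).
#' @return A data frame with one row per (regime, scale, seed):
#'   `regime`, `scale`, `seed`, `n_vertices`, `n_edges`, `n_modules`,
#'   `seconds`, `ms_per_module`.
#' @export
run_benchmark <- function(regimes = c("clique", "enriched", "dense"),
                          scales = 7:9, seeds = 1:3, edge_factor = 7,
                          min_size = 2L, index = "hierarchical") {
  rows <- list()
  for (scale in scales) {
    for (seed in seeds) {
      g <- remove_isolated(rmat_graph(scale, edge_factor, seed = seed))
      for (regime in regimes) {
        cfg <- regime_config(regime)
        q <- regime_query(regime, g$n_vertices)
        par <- dense_params(cfg$gamma, cfg$mu, min_size,
                            gamma_strict = cfg$gamma_strict)
        t0 <- proc.time()[["elapsed"]]
        mods <- enumerate_dense(g, q, par, index = index)
        el <- proc.time()[["elapsed"]] - t0
        rows[[length(rows) + 1L]] <- data.frame(
          regime = regime, scale = scale, seed = seed,
          n_vertices = g$n_vertices, n_edges = g$n_edges,
          n_modules = length(mods), seconds = el,
          ms_per_module = if (length(mods)) 1000 * el / length(mods) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
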