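# Graph container and file I/O.
#
# A dense_graph is deliberately minimal: string vertex labels, a symmetric
# adjacency list over contiguous 1-based internal indices, and edge/vertex
# counts.  All module definitions here are purely topological, so edge
# weights (e.g. STRING scores) are thresholded at read time and dropped.

new_dense_graph <- function(labels, ei, ej) {
  n <- length(labels)
  stopifnot(!anyDuplicated(labels))
  if (length(ei)) {
    stopifnot(all(ei >= 1L), all(ei <= n), all(ej >= 1L), all(ej <= n))
    keep <- ei != ej
    ei <- ei[keep]; ej <- ej[keep]
    key <- pmin(ei, ej) * (n + 1) + pmax(ei, ej)
    first <- !duplicated(key)
    ei <- ei[first]; ej <- ej[first]
  }
  f <- c(ei, ej)
  t <- c(ej, ei)
  adj <- split(as.integer(t), factor(f, levels = seq_len(n)))
  adj <- lapply(unname(adj), function(x) sort(x))
  structure(
    list(labels = as.character(labels), adj = adj,
         n_vertices = n, n_edges = length(ei)),
    class = "dense_graph")
}

as_dense_graph <- function(graph) {
  if (inherits(graph, "dense_graph")) return(graph)
  stop("`graph` must be a dense_graph (see read_edge_list(), rmat_graph())")
}

#' Build a graph from paired endpoint labels
#'
#' Vertices are created in first-appearance order; self-loops are dropped and
#' reciprocal/duplicate pairs collapse to a single undirected edge.
#'
#' @param from,to Character vectors of endpoint labels, same length.
#' @return A `dense_graph`.
#' @export
graph_from_edges <- function(from, to) {
  stopifnot(length(from) == length(to))
  from <- as.character(from)
  to <- as.character(to)
  labels <- unique(c(rbind(from, to)))
  new_dense_graph(labels, match(from, labels), match(to, labels))
}

#' @export
print.dense_graph <- function(x, ...) {
  cat(sprintf("dense_graph: %d vertices, %d edges\n", x$n_vertices, x$n_edges))
  invisible(x)
}

#' Vertex degrees of a graph
#' @param graph A `dense_graph`.
#' @return Integer vector of degrees.
#' @export
graph_degrees <- function(graph) {
  lengths(as_dense_graph(graph)$adj)
}

# edge matrix (2 columns of internal indices, each undirected edge once)
graph_edge_matrix <- function(graph) {
  adj <- graph$adj
  ei <- rep.int(seq_along(adj), lengths(adj))
  ej <- unlist(adj, use.names = FALSE)
  keep <- ei < ej
  cbind(ei[keep], ej[keep])
}

#' Read an undirected graph from a whitespace-separated edge list
#'
#' Each non-comment line names one edge by its two endpoint labels (extra
#' columns are ignored).  Self-loops are dropped, duplicate and reciprocal
#' lines collapse, and vertices get internal indices in first-appearance
#' order.
#'
#' @param path File path.
#' @param comment_prefix Lines starting with this prefix are skipped.
#' @return A `dense_graph`.
#' @export
read_edge_list <- function(path, comment_prefix = "#") {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  idx <- seq_along(lines)
  keep <- !startsWith(trimws(lines), comment_prefix) & nzchar(trimws(lines))
  lines <- lines[keep]
  idx <- idx[keep]
  if (length(lines) == 0L) stop("empty edge list: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    stop("malformed edge list line ", idx[which(nt < 2L)[1]],
         " in ", path, ": fewer than 2 tokens")
  }
  graph_from_edges(vapply(toks, `[`, "", 1L), vapply(toks, `[`, "", 2L))
}

#' Read a STRING-style protein.links file
#'
#' Expects rows of `protein1 protein2 combined_score` (a header line is
#' tolerated).  Edges with `combined_score >= score_threshold` are kept;
#' every protein that appears in any row becomes a vertex, so low-scoring
#' rows can leave isolated vertices (see [remove_isolated()]).
#'
#' The conventional STRING "high confidence" cutoff of 700 (scores are
#' 0-1000) is the default; pass the threshold explicitly for other uses.
#'
#' @param path File path.
#' @param score_threshold Integer in 0-1000.
#' @return A `dense_graph`.
#' @export
read_string_links <- function(path, score_threshold = 700) {
  stopifnot(score_threshold >= 0, score_threshold <= 1000)
  if (!file.exists(path)) stop("STRING links file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty STRING links file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  start <- 1L
  if (lengths(toks)[1] >= 3L &&
      is.na(suppressWarnings(as.integer(toks[[1]][3])))) {
    start <- 2L  # header line
    if (length(lines) == 1L) stop("empty STRING links file: ", path)
  }
  toks <- toks[start:length(toks)]
  nt <- lengths(toks)
  if (any(nt < 3L)) {
    stop("malformed STRING links line ", which(nt < 3L)[1] + start - 1L,
         ": expected 'protein1 protein2 combined_score'")
  }
  p1 <- vapply(toks, `[`, "", 1L)
  p2 <- vapply(toks, `[`, "", 2L)
  sc <- suppressWarnings(as.integer(vapply(toks, `[`, "", 3L)))
  if (anyNA(sc)) {
    stop("malformed STRING links line ", which(is.na(sc))[1] + start - 1L,
         ": combined_score is not an integer")
  }
  labels <- unique(c(rbind(p1, p2)))
  keep <- sc >= score_threshold
  new_dense_graph(labels, match(p1[keep], labels), match(p2[keep], labels))
}

#' Read a query (knowledge-prior) vertex set
#'
#' One identifier per line.  Identifiers absent from the graph are reported
#' with a warning (count and list), not silently dropped; if none match, an
#' error is raised because enumeration would be vacuous.
#'
#' @param path File path.
#' @param graph The `dense_graph` the identifiers refer to.
#' @return Sorted integer vector of query vertex indices.
#' @export
read_query_set <- function(path, graph) {
  graph <- as_dense_graph(graph)
  if (!file.exists(path)) stop("query file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- unique(ids[nzchar(ids)])
  if (length(ids) == 0L) stop("no identifiers in query file: ", path)
  hit <- match(ids, graph$labels)
  missing <- ids[is.na(hit)]
  if (length(missing) == length(ids)) {
    stop("none of the ", length(ids), " query identifiers are in the graph")
  }
  if (length(missing)) {
    warning(length(missing), " query identifier(s) not in the graph: ",
            paste(missing, collapse = ", "))
  }
  sort(hit[!is.na(hit)])
}

#' Write an edge list
#'
#' One line per undirected edge, two tab-separated endpoint labels.
#'
#' @param graph A `dense_graph`.
#' @param path Output path.
#' @export
write_edge_list <- function(graph, path) {
  graph <- as_dense_graph(graph)
  em <- graph_edge_matrix(graph)
  writeLines(paste(graph$labels[em[, 1]], graph$labels[em[, 2]], sep = "\t"),
             path)
  invisible(NULL)
}

# per-module summary row used by write_modules() and as.data.frame
module_summary <- function(modules, graph, query) {
  graph <- as_dense_graph(graph)
  rows <- lapply(modules, function(S) {
    s <- length(S)
    dr <- if (s == 1L) 1 else
      min(vapply(S, function(v) sum(graph$adj[[v]] %in% S), 1L)) / (s - 1)
    data.frame(
      size = s,
      n_query_members = sum(S %in% query),
      density_ratio = dr,
      enrichment_ratio = sum(S %in% query) / s,
      members = paste(sort(graph$labels[S]), collapse = ","),
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(size = integer(), n_query_members = integer(),
               density_ratio = numeric(), enrichment_ratio = numeric(),
               members = character(), stringsAsFactors = FALSE)
  }
  df <- df[order(-df$size, df$members), , drop = FALSE]
  df <- cbind(module_id = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Write discovered modules as TSV
#'
#' Columns: `module_id`, `size`, `n_query_members`, `density_ratio` (minimum
#' over members of within-module degree / (size - 1); 1 for singletons),
#' `enrichment_ratio`, and the comma-joined sorted member labels.  Rows are
#' ordered by size descending, then lexicographically by member list.
#'
#' @param modules List of vertex-index vectors (e.g. from
#'   [enumerate_dense()]).
#' @param graph The `dense_graph` the indices refer to.
#' @param query Query vertex indices.
#' @param path Output path.
#' @export
write_modules <- function(modules, graph, query, path) {
  stopifnot(all(lengths(modules) > 0L))
  df <- module_summary(modules, graph, query)
  df$density_ratio <- sprintf("%.4f", df$density_ratio)
  df$enrichment_ratio <- sprintf("%.4f", df$enrichment_ratio)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}
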