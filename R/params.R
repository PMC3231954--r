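# Density / enrichment parameters and the predicates built on them.
#
# gamma and mu are user-facing real numbers, but every threshold comparison is
# done in exact integer arithmetic: each value is converted once to a rational
# p/q (continued fractions), and "at least gamma*(|S|-1) neighbours" becomes an
# integer cross-multiplication.  This avoids floating-point misrounding when
# gamma*(|S|-1) is integral (e.g. gamma = 0.85, |S| = 21).

# Best rational approximation p/q of x with q <= max_denominator.
rationalize <- function(x, max_denominator = 1000000, tol = 1e-9) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x), x >= 0)
  p0 <- 0; q0 <- 1  # convergent h_{k-2}
  p1 <- 1; q1 <- 0  # convergent h_{k-1}
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_denominator) break
    p0 <- p1; q0 <- q1
    p1 <- p2; q1 <- q2
    if (abs(x - p1 / q1) <= tol) break
    fr <- r - a
    if (fr < 1e-15) break
    r <- 1 / fr
  }
  if (q1 == 0 || abs(x - p1 / q1) > tol) {
    stop("cannot represent ", x, " as a rational with denominator <= ",
         max_denominator)
  }
  c(p = p1, q = q1)
}

#' Density and enrichment parameters for module enumeration
#'
#' Bundles the density threshold `gamma`, the enrichment threshold `mu` and
#' the minimum module size.  A vertex set S is gamma-dense when every member
#' is adjacent to at least `ceiling(gamma * (|S| - 1))` other members, and
#' mu-enriched when at least `mu * |S|` members belong to the query set.
#'
#' `gamma` normally lies in (0.5, 1]: at one half or above, any two members
#' of a dense set share a neighbour, which is what makes the distance-2
#' candidate restriction of the search valid.  The boundary `gamma = 0.5` is
#' admitted in two exactly-computed flavours: the plain `>=`-variant (every
#' vertex needs at least `(|S| - 1) / 2` neighbours; used by the `enriched`
#' benchmark regime) and, with `gamma_strict = TRUE`, the "just above one
#' half" variant (strictly more than `(|S| - 1) / 2` neighbours, i.e.
#' `gamma = 0.5 + epsilon`).
#'
#' @param gamma Density threshold in \[0.5, 1\]; values at or below 0.5 are
#'   rejected except the boundary 0.5 itself.
#' @param mu Enrichment threshold in (0, 1]. The default 0.001 keeps every
#'   dense module that contains at least one query vertex (for module sizes
#'   up to 1000).
#' @param min_size Minimum module size to report (integer >= 1; default 2,
#'   since singletons are vacuously dense).
#' @param gamma_strict If `TRUE`, the degree requirement is "strictly more
#'   than gamma * (|S| - 1)" rather than "at least".
#' @return An object of class `dense_params`.
#' @examples
#' dense_params(0.75, 0.001)
#' dense_params(0.5, 0.9, gamma_strict = TRUE)  # the "just above half" regime
#' @export
dense_params <- function(gamma = 0.75, mu = 0.001, min_size = 2L,
                         gamma_strict = FALSE) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L,
            is.numeric(mu), length(mu) == 1L,
            length(min_size) == 1L, min_size >= 1, min_size == floor(min_size),
            is.logical(gamma_strict), length(gamma_strict) == 1L)
  if (gamma < 0.5 || gamma > 1) {
    stop("gamma must lie in the interval (0.5, 1] (the boundary 0.5 is ",
         "admitted only as the >=-variant or with gamma_strict = TRUE); got ",
         gamma)
  }
  if (mu <= 0 || mu > 1) stop("mu must lie in the interval (0, 1]; got ", mu)
  g <- rationalize(gamma)
  m <- rationalize(mu)
  structure(
    list(gamma = gamma, mu = mu, min_size = as.integer(min_size),
         gamma_strict = gamma_strict,
         gp = unname(g["p"]), gq = unname(g["q"]),
         mp = unname(m["p"]), mq = unname(m["q"])),
    class = "dense_params")
}

#' @export
print.dense_params <- function(x, ...) {
  cat(sprintf("dense_params: gamma = %g%s (%d/%d), mu = %g (%d/%d), min_size = %d\n",
              x$gamma, if (x$gamma_strict) "+ (strict)" else "",
              x$gp, x$gq, x$mu, x$mp, x$mq, x$min_size))
  invisible(x)
}

as_dense_params <- function(params) {
  if (inherits(params, "dense_params")) return(params)
  stop("`params` must be created with dense_params()")
}

# minimal integer k with k >= (p/q)*m (k > when strict); m >= 0
rat_min_degree <- function(p, q, m, strict = FALSE) {
  out <- if (strict) (p * m) %/% q + 1 else (p * m + q - 1) %/% q
  out[m <= 0] <- 0
  out
}

#' Minimum within-module degree required at a given module size
#'
#' Returns `ceiling(gamma * (size - 1))`, the number of neighbours each
#' member of a gamma-dense set of `size` vertices must have inside the set.
#' Computed in exact rational arithmetic.
#'
#' @param gamma Density threshold (see [dense_params()]).
#' @param size Module size(s), integer >= 1. Vectorized.
#' @param strict If `TRUE`, requires strictly more than `gamma * (size - 1)`.
#' @return Integer vector of required degrees.
#' @examples
#' required_degree(0.75, 5)   # 3
#' required_degree(0.999, 4)  # 3: clique behaviour below size 1001
#' required_degree(1, 7)      # 6
#' @export
required_degree <- function(gamma, size, strict = FALSE) {
  stopifnot(all(size >= 1))
  if (gamma < 0.5 || gamma > 1)
    stop("gamma must lie in the interval (0.5, 1]")
  r <- rationalize(gamma)
  as.integer(rat_min_degree(r["p"], r["q"], size - 1, strict))
}

#' Is a vertex set gamma-dense?
#'
#' Checks that every vertex of `S` has at least
#' `required_degree(gamma, length(S))` neighbours inside `S`.  A singleton is
#' vacuously dense.
#'
#' @param graph A `dense_graph`.
#' @param S Vertex indices (non-empty).
#' @param gamma Density threshold.
#' @param strict See [dense_params()].
#' @return `TRUE` or `FALSE`.
#' @export
is_gamma_dense <- function(graph, S, gamma, strict = FALSE) {
  graph <- as_dense_graph(graph)
  S <- as.integer(S)
  if (length(S) == 0L) stop("S must be non-empty")
  stopifnot(all(S >= 1L), all(S <= graph$n_vertices), !anyDuplicated(S))
  need <- required_degree(gamma, length(S), strict)
  for (v in S) {
    if (sum(graph$adj[[v]] %in% S) < need) return(FALSE)
  }
  TRUE
}

#' Is a vertex set mu-enriched with respect to a query set?
#'
#' `TRUE` when at least `mu * length(S)` members of `S` belong to `query`,
#' evaluated by exact cross-multiplication.
#'
#' @param S Vertex indices (non-empty).
#' @param query Query vertex indices.
#' @param mu Enrichment threshold in (0, 1].
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_mu_enriched(1:5, c(1, 2), 0.4)  # TRUE: 2 >= 0.4 * 5
#' is_mu_enriched(1:5, c(1, 2), 0.5)  # FALSE: 2 < 2.5
#' @export
is_mu_enriched <- function(S, query, mu) {
  if (length(S) == 0L) stop("S must be non-empty")
  if (mu <= 0 || mu > 1) stop("mu must lie in the interval (0, 1]")
  r <- rationalize(mu)
  nq <- sum(S %in% query)
  unname(nq * r["q"] >= r["p"] * length(S))
}
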