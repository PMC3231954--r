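# Module registries ("which discovered module contains all of these
# vertices?").  Two backings with identical semantics:
#
#   flat          - one bitset per vertex (bit i = membership in module i),
#                   superset queries AND the full bitsets;
#   hierarchical  - the same bitsets plus summary layers in which one bit
#                   records whether a byte of the layer below is nonzero
#                   (a new layer is added whenever the top layer outgrows
#                   one byte), so AND queries skip all-zero byte ranges.
#
# The enumerator embeds these structures directly; the handles here expose
# them for standalone use and for the equivalence tests.

#' Create a module registry
#'
#' @param kind `"hierarchical"` (default) or `"flat"`.
#' @return A `module_index` handle.
#' @examples
#' idx <- module_index()
#' index_register(idx, c(1, 2, 3))
#' index_has_superset(idx, c(1, 2))  # TRUE
#' index_has_superset(idx, c(1, 4))  # FALSE
#' @export
module_index <- function(kind = c("hierarchical", "flat")) {
  kind <- match.arg(kind)
  ptr <- cpp_index_new(if (kind == "flat") 1L else 2L)
  structure(list(ptr = ptr, kind = kind), class = "module_index")
}

as_module_index <- function(index) {
  if (inherits(index, "module_index")) return(index)
  stop("`index` must be created with module_index()")
}

check_index_vertices <- function(vertices) {
  vertices <- as.integer(vertices)
  if (length(vertices) == 0L) stop("vertex set must be non-empty")
  stopifnot(all(vertices >= 1L), !anyDuplicated(vertices))
  vertices
}

#' Register a module in a registry
#'
#' Modules receive sequential ids starting at 0; the id bit is set in the
#' membership bitset of every member vertex and all summary layers are
#' updated.
#'
#' @param index A `module_index`.
#' @param vertices Non-empty vector of vertex indices (any positive
#'   integers; storage grows lazily per vertex).
#' @return The assigned module id (invisibly).
#' @export
index_register <- function(index, vertices) {
  index <- as_module_index(index)
  invisible(cpp_index_register(index$ptr, check_index_vertices(vertices) - 1L))
}

#' Does some registered module contain all of these vertices?
#'
#' Computed by AND-ing the members' bitsets; the hierarchical backing
#' descends only into byte ranges whose summary AND is nonzero.  A vertex
#' never seen by [index_register()] has an empty bitset, so the answer is
#' `FALSE`.
#'
#' @param index A `module_index`.
#' @param vertices Non-empty vector of vertex indices.
#' @return `TRUE` or `FALSE`.
#' @export
index_has_superset <- function(index, vertices) {
  index <- as_module_index(index)
  cpp_index_superset(index$ptr, check_index_vertices(vertices) - 1L)
}

#' Number of modules registered so far
#' @param index A `module_index`.
#' @return Integer count.
#' @export
index_size <- function(index) {
  cpp_index_count(as_module_index(index)$ptr)
}

#' Per-vertex membership counts (debug dump)
#'
#' @param index A `module_index`.
#' @return A data frame with columns `vertex` and `n_modules`, one row per
#'   vertex that belongs to at least one registered module.
#' @export
index_bit_counts <- function(index) {
  cpp_index_bit_counts(as_module_index(index)$ptr)
}

#' @export
print.module_index <- function(x, ...) {
  cat(sprintf("module_index (%s): %d module(s) registered\n",
              x$kind, index_size(x)))
  invisible(x)
}
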