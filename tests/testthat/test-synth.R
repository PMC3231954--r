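test_that("R-MAT graphs have the exact requested size and are simple", {
  g <- rmat_graph(scale = 3, edge_factor = 3, seed = 10)
  expect_equal(g$n_vertices, 8L)
  expect_equal(g$n_edges, 24L)
  for (v in seq_len(g$n_vertices)) {
    expect_false(v %in% g$adj[[v]])
    expect_false(anyDuplicated(g$adj[[v]]) > 0)
    for (u in g$adj[[v]]) expect_true(v %in% g$adj[[u]])
  }
  # mean degree is exactly 2 * edge_factor before isolated removal
  g2 <- rmat_graph(scale = 6, edge_factor = 7, seed = 2)
  expect_equal(mean(lengths(g2$adj)), 14)
  expect_error(rmat_graph(3, 10, seed = 1), "at most")
  expect_error(rmat_graph(3, 3, a = 0.5, seed = 1), "sum to 1")
})

test_that("R-MAT generation is deterministic and leaves the RNG untouched", {
  set.seed(555)
  before <- .Random.seed
  g1 <- rmat_graph(5, 4, seed = 77)
  expect_identical(.Random.seed, before)
  g2 <- rmat_graph(5, 4, seed = 77)
  expect_identical(g1, g2)
  g3 <- rmat_graph(5, 4, seed = 78)
  expect_false(identical(g1$adj, g3$adj))
})

test_that("default quadrant skew produces heavy-tailed degrees", {
  ratio <- vapply(1:10, function(s) {
    d <- lengths(rmat_graph(10, 7, seed = s)$adj)
    max(d) / mean(d)
  }, 1)
  expect_gt(mean(ratio), 3)
})

test_that("isolated-vertex removal keeps labels, edges and degrees intact", {
  g <- graph_n(4, c(1, 2, 3), c(2, 3, 1))
  r <- remove_isolated(g)
  expect_equal(r$n_vertices, 3L)
  expect_equal(r$n_edges, 3L)
  expect_equal(r$labels, c("x1", "x2", "x3"))
  full <- cycle_graph(5)
  expect_identical(remove_isolated(full), full)
  # scale-7 graphs keep close to all 128 vertices, as in the benchmark design
  nv <- vapply(1:10, function(s)
    remove_isolated(rmat_graph(7, 7, seed = s))$n_vertices, 1L)
  expect_true(all(nv <= 128) && all(nv >= 120))
})

test_that("planted modules are dense by construction and carry query marks", {
  base <- er_graph(50, 0.02, seed = 6)
  pl <- plant_module(base, size = 6, gamma = 1, query_fraction = 0.5, seed = 8)
  expect_length(pl$planted, 6)
  expect_true(is_gamma_dense(pl$graph, pl$planted, 1))  # K6 present
  expect_length(pl$query, 3)
  expect_true(all(pl$query %in% pl$planted))
  expect_error(plant_module(base, 1, 0.75, 0.5, seed = 1), "at least 2")
  # query_fraction 0: no query additions, and with a disjoint query set the
  # planted module is gated out by enrichment
  pl0 <- plant_module(base, size = 8, gamma = 0.75, query_fraction = 0,
                      seed = 9)
  expect_length(pl0$query, 0)
  outside <- setdiff(seq_len(base$n_vertices), pl0$planted)[1]
  mods <- enumerate_dense(pl0$graph, outside, dense_params(0.75, 0.5))
  expect_false(any(vapply(mods, function(m) all(pl0$planted %in% m), TRUE)))
})

test_that("a module planted in an empty background is recovered exactly", {
  empty <- graph_n(50, integer(0), integer(0))
  pl <- plant_module(empty, size = 8, gamma = 0.75, query_fraction = 0.5,
                     seed = 21)
  mods <- enumerate_dense(pl$graph, pl$query, dense_params(0.75, 0.5))
  expect_true(any(vapply(mods, function(m) all(pl$planted %in% m), TRUE)))
})
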