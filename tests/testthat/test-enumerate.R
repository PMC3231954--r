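test_that("initial candidate universe is the distance-2 neighbourhood", {
  star <- graph_n(4, c(1, 1, 1), c(2, 3, 4))
  expect_equal(initial_candidates(star, 1), 2:4)
  expect_equal(initial_candidates(path_graph(4), 1), 2:3)  # distance-3 excluded
  lone <- graph_n(3, 1, 2)
  expect_equal(initial_candidates(lone, 3), integer(0))
})

test_that("expansion feasibility bound matches the hand-checked cases", {
  # with no candidates it reduces to the density predicate
  expect_true(extension_feasible(cycle_graph(3), 1:3, integer(0), 0.75))
  expect_false(extension_feasible(path_graph(3), 1:3, integer(0), 0.75))
  # S = edge {1,2}; c adjacent to both -> feasible at gamma 0.75
  tri <- cycle_graph(3)
  expect_true(extension_feasible(tri, 1:2, 3L, 0.75))
  # c adjacent only to one endpoint: vertex 2 has c_a = 0, so its own bound
  # is the size-2 one (1 >= 1) and the necessary condition still passes,
  # even though brute force shows no dense supergraph actually exists --
  # the bound prunes conservatively, never exactly
  g <- graph_n(3, c(1, 1), c(2, 3))
  expect_true(extension_feasible(g, 1:2, 3L, 0.75))
  bf <- brute_force_maximal(g, 1:3, dense_params(0.75, 0.001))
  expect_false(any(vapply(bf, function(m) all(1:2 %in% m) && length(m) > 2,
                          TRUE)))
  # a candidate adjacent to neither member leaves some s_a + c_a below even
  # the size-2 requirement once |S| grows
  g2 <- graph_n(4, c(1, 3), c(2, 4))
  expect_false(extension_feasible(g2, c(1L, 2L, 3L), 4L, 0.75))
})

test_that("candidate degree pruning keeps feasible vertices, removes dead ones", {
  k5 <- complete_graph(5)
  expect_equal(prune_candidates_density(k5, 1:2, 3:5, 0.999), 3:5)
  # candidate with no neighbours in S or C is removed once |S| >= 2, and a
  # candidate adjacent to all of S survives
  g <- graph_n(4, c(1, 1, 2), c(2, 3, 3))
  expect_equal(prune_candidates_density(g, 1:2, c(3L, 4L), 0.75), 3L)
  # adjacent to only one member of S: even its best-case extension stays
  # below the ceiling, so it is removed as well
  g2 <- graph_n(4, c(1, 1), c(2, 3))
  expect_equal(prune_candidates_density(g2, 1:2, c(3L, 4L), 0.75),
               integer(0))
})

test_that("degree pruning never discards a vertex of any maximal module", {
  densemod:::local_seed(909, {
    for (rep in 1:40) {
      g <- er_graph(10, sample(c(0.3, 0.5), 1), sample.int(1e6, 1))
      gamma <- sample(c(0.55, 0.75), 1)
      bf <- brute_force_maximal(g, seq_len(g$n_vertices),
                                dense_params(gamma, 0.001))
      v0 <- sample.int(g$n_vertices, 1)
      C0 <- initial_candidates(g, v0)
      Cp <- prune_candidates_density(g, v0, C0, gamma)
      removed <- setdiff(C0, Cp)
      for (m in bf) {
        if (v0 %in% m) expect_length(intersect(removed, m), 0)
      }
    }
  })
})

test_that("enrichment feasibility bound and vertex-removal rule", {
  g <- complete_graph(6)
  # Q covers S and C: always feasible
  expect_true(prune_enrichment(g, 1:2, 3:4, 1:6, 1)$feasible)
  # no query member anywhere: dead branch even at mu = 0.001
  expect_false(prune_enrichment(g, 1L, integer(0), 6L, 0.001)$feasible)
  # |S|=3, |S/\Q|=2, |C/\Q|=1: 3 >= 0.9*4 fails
  expect_false(prune_enrichment(g, 1:3, 4:6, c(1, 2, 4), 0.9)$feasible)
  # non-query candidate whose addition forces violation is dropped
  pr <- prune_enrichment(g, 1L, c(2L, 3L), c(1L, 2L), 0.9)
  expect_true(pr$feasible)
  expect_equal(pr$candidates, 2L)  # 3 is non-query and kills the bound
})

test_that("enumeration matches the spec's small worked examples", {
  k4 <- complete_graph(4)
  expect_equal(canon(enumerate_dense(k4, 2, dense_params(0.75, 0.001))),
               "1,2,3,4")
  # two triangles sharing vertex 1: overlapping modules both reported
  bowtie <- graph_n(5, c(1, 1, 2, 1, 1, 4), c(2, 3, 3, 4, 5, 5))
  expect_equal(canon(enumerate_dense(bowtie, 1, dense_params(0.75, 0.001))),
               c("1,2,3", "1,4,5"))
  p4 <- path_graph(4)
  expect_equal(canon(enumerate_dense(p4, 1:4, dense_params(0.75, 0.001))),
               c("1,2", "2,3", "3,4"))
})

test_that("returned modules always satisfy both predicates and min size", {
  suite <- make_suite(25, seed = 31)
  for (case in suite) {
    par <- dense_params(0.75, 0.5, 3)
    mods <- enumerate_dense(case$graph, case$query, par)
    for (m in mods) {
      expect_gte(length(m), 3)
      expect_true(is_gamma_dense(case$graph, m, 0.75))
      expect_true(is_mu_enriched(m, case$query, 0.5))
    }
  }
})

test_that("every returned module contains a query vertex, so query seeding is complete", {
  suite <- make_suite(25, seed = 77)
  for (case in suite) {
    mods <- enumerate_dense(case$graph, case$query, dense_params(0.75, 0.001))
    for (m in mods) expect_gte(length(intersect(m, case$query)), 1)
  }
})

test_that("all pairs inside a module sit within distance 2 of each other", {
  suite <- make_suite(20, seed = 55)
  for (case in suite) {
    g <- case$graph
    mods <- enumerate_dense(g, case$query, dense_params(0.55, 0.001))
    for (m in mods) {
      for (v in m) {
        reach2 <- unique(c(v, g$adj[[v]],
                           unlist(g$adj[g$adj[[v]]], use.names = FALSE)))
        expect_true(all(m %in% reach2))
      }
    }
  }
})

test_that("tightening gamma or mu only shrinks modules into looser ones", {
  suite <- make_suite(15, seed = 99)
  contained_in_some <- function(m, mods) {
    any(vapply(mods, function(M) all(m %in% M), TRUE))
  }
  for (case in suite) {
    loose_mu <- enumerate_dense(case$graph, case$query,
                                dense_params(0.75, 0.2))
    tight_mu <- enumerate_dense(case$graph, case$query,
                                dense_params(0.75, 0.8))
    for (m in tight_mu) expect_true(contained_in_some(m, loose_mu))
    loose_g <- enumerate_dense(case$graph, case$query,
                               dense_params(0.55, 0.001))
    tight_g <- enumerate_dense(case$graph, case$query,
                               dense_params(0.999, 0.001))
    for (m in tight_g) expect_true(contained_in_some(m, loose_g))
  }
})

test_that("runs are deterministic: identical output sets in identical order", {
  suite <- make_suite(10, seed = 13)
  for (case in suite) {
    a <- enumerate_dense(case$graph, case$query, dense_params(0.75, 0.001))
    b <- enumerate_dense(case$graph, case$query, dense_params(0.75, 0.001))
    expect_identical(unclass(a)[seq_along(a)], unclass(b)[seq_along(b)])
  }
})

test_that("maximality filter removes strict subsets and duplicates only", {
  expect_equal(maximality_filter(list(c(1L, 2L), c(1L, 2L, 3L))),
               list(c(1L, 2L, 3L)))
  expect_equal(maximality_filter(list(c(1L, 2L), c(2L, 3L))),
               list(c(1L, 2L), c(2L, 3L)))
  expect_equal(maximality_filter(list()), list())
  expect_equal(maximality_filter(list(c(1L, 2L), c(2L, 1L))), list(c(1L, 2L)))
  # validating variant rejects an infeasible input set
  expect_error(
    maximality_filter(list(1:3), path_graph(3), 1:3, dense_params(0.75, 0.001)),
    "violates")
})

test_that("invalid enumeration inputs raise domain errors", {
  k4 <- complete_graph(4)
  expect_error(enumerate_dense(k4, integer(0), dense_params(0.75, 0.001)),
               "non-empty")
  expect_error(enumerate_dense(k4, 1, list(gamma = 0.75)), "dense_params")
})
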