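test_that("edge lists parse with dedup, self-loop dropping and stable indices", {
  f <- withr::local_tempfile(lines = c("a b", "b c"))
  g <- read_edge_list(f)
  expect_equal(g$n_vertices, 3L)
  expect_equal(g$n_edges, 2L)
  expect_equal(g$labels, c("a", "b", "c"))  # first-appearance order

  f2 <- withr::local_tempfile(lines = c("a b", "b a", "a a"))
  g2 <- read_edge_list(f2)
  expect_equal(g2$n_vertices, 2L)
  expect_equal(g2$n_edges, 1L)

  f3 <- withr::local_tempfile(lines = c("# comment", "a b", "", "c d e"))
  g3 <- read_edge_list(f3)
  expect_equal(g3$n_edges, 2L)  # third column ignored
})

test_that("malformed or empty edge lists raise parse errors naming the line", {
  f <- withr::local_tempfile(lines = "a")
  expect_error(read_edge_list(f), "line 1")
  f2 <- withr::local_tempfile(lines = c("a b", "c"))
  expect_error(read_edge_list(f2), "line 2")
  f3 <- withr::local_tempfile(lines = character(0))
  expect_error(read_edge_list(f3), "empty")
})

test_that("graph invariants hold after reading: symmetry, no loops, edge count", {
  f <- withr::local_tempfile(lines = c("a b", "b c", "c a", "c d", "b c"))
  g <- read_edge_list(f)
  for (v in seq_len(g$n_vertices)) {
    expect_false(v %in% g$adj[[v]])
    for (u in g$adj[[v]]) expect_true(v %in% g$adj[[u]])
  }
  expect_equal(sum(lengths(g$adj)) / 2, g$n_edges)
})

test_that("STRING links are thresholded at read time, keeping isolated proteins", {
  f <- withr::local_tempfile(lines = c("protein1 protein2 combined_score",
                                       "p1 p2 900", "p1 p3 400"))
  g <- read_string_links(f, 700)
  expect_equal(g$n_vertices, 3L)  # p3 kept, isolated
  expect_equal(g$n_edges, 1L)
  expect_equal(remove_isolated(g)$n_vertices, 2L)

  f2 <- withr::local_tempfile(lines = c("p1 p2 900", "p2 p1 900"))
  expect_equal(read_string_links(f2, 700)$n_edges, 1L)  # header optional

  f3 <- withr::local_tempfile(lines = c("protein1 protein2 combined_score",
                                        "p1 p2 high"))
  expect_error(read_string_links(f3, 700), "combined_score")
})

test_that("STRING reader at threshold 0 equals the plain edge-list reader", {
  densemod:::local_seed(11, {
    lab <- paste0("p", 1:12)
    ei <- sample(lab, 30, replace = TRUE)
    ej <- sample(lab, 30, replace = TRUE)
    sc <- sample(0:1000, 30, replace = TRUE)
  })
  f1 <- withr::local_tempfile(lines = paste(ei, ej, sc))
  f2 <- withr::local_tempfile(lines = paste(ei, ej))
  gs <- read_string_links(f1, 0)
  ge <- read_edge_list(f2)
  expect_equal(gs$labels, ge$labels)
  expect_equal(gs$adj, ge$adj)
})

test_that("query sets resolve against the graph with warnings for misses", {
  gf <- withr::local_tempfile(lines = c("a b", "b c"))
  g <- read_edge_list(gf)
  q1 <- withr::local_tempfile(lines = c("a", "c"))
  expect_equal(read_query_set(q1, g), c(1L, 3L))
  q2 <- withr::local_tempfile(lines = c("a", "z"))
  expect_warning(res <- read_query_set(q2, g), "z")
  expect_equal(res, 1L)
  q3 <- withr::local_tempfile(lines = "z")
  expect_error(suppressWarnings(read_query_set(q3, g)), "none")
})

test_that("module TSV has the documented columns, values and row order", {
  g <- graph_from_edges(c("a", "a", "b", "d"), c("b", "c", "c", "e"))
  out <- withr::local_tempfile()
  write_modules(list(c(1L, 2L, 3L), c(4L, 5L)), g, query = 1L, out)
  df <- read.delim(out)
  expect_equal(names(df), c("module_id", "size", "n_query_members",
                            "density_ratio", "enrichment_ratio", "members"))
  expect_equal(df$size, c(3L, 2L))  # larger module first
  expect_equal(df$members[1], "a,b,c")
  expect_equal(df$density_ratio[1], 1)      # triangle
  expect_equal(df$enrichment_ratio[1], 0.3333)
  expect_equal(df$n_query_members, c(1L, 0L))

  write_modules(list(), g, query = 1L, out)
  expect_equal(nrow(read.delim(out)), 0L)  # header only
})

test_that("write + re-read round trip preserves labels and edges", {
  g <- remove_isolated(rmat_graph(5, 3, seed = 3))
  f <- withr::local_tempfile()
  write_edge_list(g, f)
  g2 <- read_edge_list(f)
  expect_setequal(g2$labels, g$labels)
  e1 <- apply(densemod:::graph_edge_matrix(g), 1,
              function(e) paste(sort(g$labels[e]), collapse = "-"))
  e2 <- apply(densemod:::graph_edge_matrix(g2), 1,
              function(e) paste(sort(g2$labels[e]), collapse = "-"))
  expect_setequal(e2, e1)
})
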