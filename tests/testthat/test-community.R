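two_triangles_bridge <- function() {
  make_net("a", "b", "b", "c", "c", "a", "d", "e", "e", "f", "f", "d", "a", "d")
}

test_that("modularity closed forms: one module gives 0, two split cliques give 0.5", {
  g <- make_net("A", "B", "B", "C", "C", "A")
  expect_identical(modularity_q(g, c(A = 1, B = 1, C = 1)), 0)

  g2 <- make_net("A", "B", "B", "C", "C", "A", "D", "E", "E", "F", "F", "D")
  split <- c(A = 1, B = 1, C = 1, D = 2, E = 2, F = 2)
  expect_identical(modularity_q(g2, split), 0.5)

  expect_error(modularity_q(g, c(A = 1, B = 1)), "cover every")
  expect_error(modularity_q(make_net(isolated = c("A", "B")), c(A = 1, B = 2)),
               "edgeless")
})

test_that("modularity_q agrees with igraph's independent implementation", {
  for (seed in 1:8) {
    g <- random_named_gnp(15, 0.25, seed)
    set.seed(seed + 100)
    memb <- sample(1:4, 15, replace = TRUE)
    names(memb) <- igraph::V(g)$name
    if (igraph::ecount(g) == 0) next
    expect_equal(modularity_q(g, memb),
                 igraph::modularity(g, memb[igraph::V(g)$name]),
                 tolerance = 1e-12)
  }
})

test_that("random assignments have modularity near zero on average", {
  g <- random_named_gnp(80, 0.3, 9)
  set.seed(42)
  qs <- replicate(1000, {
    memb <- stats::setNames(sample(1:3, 80, replace = TRUE), igraph::V(g)$name)
    modularity_q(g, memb)
  })
  expect_lt(abs(mean(qs)), 0.02)
})

test_that("edge betweenness splits two bridged triangles into the triangles", {
  part <- detect_communities(two_triangles_bridge())
  expect_equal(part$n_modules, 2)
  m <- stats::setNames(part$membership$module, part$membership$gene)
  expect_length(unique(m[c("a", "b", "c")]), 1)
  expect_length(unique(m[c("d", "e", "f")]), 1)
  expect_false(m[["a"]] == m[["d"]])
  # reported Q matches an independent recomputation and the exhaustive optimum
  expect_equal(part$modularity, modularity_q(two_triangles_bridge(), m))
  expect_equal(part$modularity, max_modularity_exhaustive(two_triangles_bridge()))
})

test_that("degenerate partitions: edgeless network gives singletons, clique one module", {
  g <- make_net(isolated = c("x", "y", "z"))
  expect_warning(part <- detect_communities(g), "Edgeless")
  expect_equal(part$n_modules, 3)
  expect_true(is.na(part$modularity))

  clique <- igraph::make_full_graph(6)
  igraph::V(clique)$name <- letters[1:6]
  part <- detect_communities(clique)
  expect_equal(part$n_modules, 1)
  expect_equal(part$modularity, 0)

  expect_error(detect_communities(igraph::make_empty_graph(0)), "vertices must be named|empty")
})

test_that("module ids are deterministic: decreasing size, ties by smallest member", {
  # triangle d-e-f plus larger block a-b-c-g (4 nodes) via two components
  g <- make_net("a", "b", "b", "c", "c", "a", "a", "g", "b", "g", "c", "g",
                "d", "e", "e", "f", "f", "d")
  part <- detect_communities(g)
  m <- stats::setNames(part$membership$module, part$membership$gene)
  expect_equal(unname(m[c("a", "d")]), c(1, 2))  # bigger module first
  expect_equal(sort(unique(part$membership$module)), seq_len(part$n_modules))
  # repeated runs identical
  part2 <- detect_communities(g)
  expect_identical(part$membership, part2$membership)
})

test_that("both methods recover planted blocks (ARI >= 0.9)", {
  for (method in c("edge_betweenness", "leading_eigenvector")) {
    hits <- vapply(1:5, function(seed) {
      tb <- two_block_graph(10, seed)
      part <- detect_communities(tb$graph, method)
      memb <- part$membership$module[match(igraph::V(tb$graph)$name,
                                           part$membership$gene)]
      mclust::adjustedRandIndex(memb, tb$truth)
    }, numeric(1))
    expect_gte(stats::median(hits), 0.9)
  }
})

test_that("edge-betweenness partitions are near-optimal on small graphs", {
  fixtures <- list(
    two_triangles_bridge(),
    make_net("a", "b", "b", "c", "c", "d", "d", "a"),            # 4-cycle
    make_net("a", "b", "a", "c", "a", "d", "a", "e"),            # star
    {g <- igraph::make_full_graph(4); igraph::V(g)$name <- letters[1:4]
     g2 <- igraph::make_full_graph(4); igraph::V(g2)$name <- letters[5:8]
     igraph::add_edges(igraph::disjoint_union(g, g2), c("d", "e"))}  # two K4 + bridge
  )
  for (g in fixtures) {
    part <- detect_communities(g, "edge_betweenness")
    expect_gte(part$modularity, 0.95 * max_modularity_exhaustive(g))
  }
})

test_that("tidy and glance expose the partition as tables", {
  part <- detect_communities(two_triangles_bridge())
  td <- tidy(part)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("gene", "module"))
  gl <- glance(part)
  expect_equal(gl$n_modules, 2)
  expect_equal(gl$modularity, part$modularity)
})
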