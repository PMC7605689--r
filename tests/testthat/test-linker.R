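test_that("candidate linkers are exactly the unaltered neighbors of altered genes", {
  # path A-L-B
  g <- make_net("A", "L", "L", "B")
  expect_equal(find_candidate_linkers(g, c("A", "B")), "L")

  # clique of altered genes only: no candidates
  g <- make_net("A", "B", "B", "C", "C", "A")
  expect_equal(find_candidate_linkers(g, c("A", "B", "C")), character())

  # star: unaltered center with 3 of 5 leaves altered
  g <- make_net("C", "l1", "C", "l2", "C", "l3", "C", "l4", "C", "l5")
  expect_equal(find_candidate_linkers(g, c("l1", "l2", "l3")), "C")

  # altered genes neighboring altered genes are never candidates
  g <- make_net("A", "B", "B", "L")
  expect_equal(find_candidate_linkers(g, c("A", "B")), "L")
})

test_that("hypergeometric tail p matches hand-derived and enumerated values", {
  expect_identical(linker_pvalue(10, 4, 3, 0), 1)           # whole support
  expect_equal(linker_pvalue(10, 4, 3, 3), 4 / 120)         # C(4,3)/C(10,3)
  expect_equal(linker_pvalue(10, 4, 3, 3), hyper_tail_enum(10, 4, 3, 3))
  expect_equal(linker_pvalue(12, 5, 4, 2), hyper_tail_enum(12, 5, 4, 2))
  expect_error(linker_pvalue(10, 4, 5, 6), "0 <= x <= k")
  expect_error(linker_pvalue(10, 11, 3, 1), "A <= N")
})

test_that("tail equals the sum of point probabilities from x to k", {
  set.seed(101)
  for (i in 1:40) {
    N <- sample(4:40, 1)
    A <- sample(0:N, 1)
    k <- sample(1:min(N, 10), 1)
    x <- sample(0:k, 1)
    tail <- linker_pvalue(N, A, k, x, mode = "tail")
    pts <- sum(linker_pvalue(N, A, rep(k, k - x + 1), x:k, mode = "point"))
    expect_equal(tail, pts, tolerance = 1e-12)
  }
})

test_that("tail p-value is monotone in x and in the population size", {
  p_by_x <- linker_pvalue(20, 8, 6, 0:6)
  expect_true(all(diff(p_by_x) <= 1e-15))
  # growing the population with the altered count fixed dilutes the altered
  # fraction, so observing >= x altered neighbors only gets rarer
  p_by_N <- vapply(10:40, function(N) linker_pvalue(N, 5, 4, 3), numeric(1))
  expect_true(all(diff(p_by_N) <= 1e-15))
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(adjust_pvalues(0.2), 0.2)                       # n = 1 identity
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(rep(0.4, 7)), rep(0.4, 7))       # all-equal unchanged
  set.seed(7)
  p <- runif(25)
  expect_equal(adjust_pvalues(p), bh_textbook(p))
  expect_error(adjust_pvalues(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_pvalues(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("extended network covers all candidates and honors the cutoff", {
  # path A-L-B: N = 2 (3 nodes minus the candidate), A = 2, k = 2, x = 2 -> p = 1
  g <- make_net("A", "L", "L", "B")
  ext <- build_extended_network(g, c("A", "B"), cutoff = 0.05)
  expect_equal(nrow(ext$linkers), 1)
  expect_equal(ext$linkers$p_raw, 1)  # all 2 possible neighbors are altered by force
  expect_false(ext$linkers$accepted)

  # degenerate cutoff 1: everything accepted
  ext1 <- build_extended_network(g, c("A", "B"), cutoff = 1)
  expect_true(all(ext1$linkers$accepted))
  expect_setequal(igraph::V(ext1$graph)$name, c("A", "L", "B"))
  expect_equal(ext1$nodes$role[ext1$nodes$gene == "L"], "linker")

  # linker table is sorted by raw p-value
  tb <- two_block_graph(8, seed = 2)
  altered <- igraph::V(tb$graph)$name[c(1:6, 9:14)]
  ext2 <- build_extended_network(tb$graph, altered, cutoff = 0.5)
  expect_false(is.unsorted(ext2$linkers$p_raw))
})

test_that("disconnected altered genes are dropped or raise the dedicated error", {
  # two altered genes with no edges at all
  g <- make_net("C", "D", isolated = c("A", "B"))
  expect_error(build_extended_network(g, c("A", "B")), "no connected altered genes")

  # one connected pair plus one isolated altered gene: isolated is reported
  g <- make_net("A", "B", isolated = "Z")
  ext <- build_extended_network(g, c("A", "B", "Z"), cutoff = 0.05)
  expect_equal(ext$isolated_altered, "Z")
  expect_setequal(igraph::V(ext$graph)$name, c("A", "B"))
})

test_that("population size reacts to isolated nodes in the prior network", {
  g1 <- make_net("A", "L", "L", "B", "A", "B", "L", "U")
  g2 <- igraph::add_vertices(g1, 3, name = c("i1", "i2", "i3"))
  p1 <- build_extended_network(g1, c("A", "B"), cutoff = 1)$linkers
  p2 <- build_extended_network(g2, c("A", "B"), cutoff = 1)$linkers
  l1 <- p1$p_raw[p1$gene == "L"]
  l2 <- p2$p_raw[p2$gene == "L"]
  expect_lt(l2, l1)  # larger population makes 2/2 altered neighbors rarer
  # and the values agree with direct enumeration over the respective N
  expect_equal(l1, hyper_tail_enum(N = 3, A = 2, k = 3, x = 2))
  expect_equal(l2, hyper_tail_enum(N = 6, A = 2, k = 3, x = 2))
})

test_that("acceptance boundary is inclusive: p_adjusted equal to the cutoff passes", {
  # single candidate L whose only neighbor is the sole altered gene in a
  # 21-node network: p = A/N = 1/20, which the point-mode computation yields
  # as exactly the double 0.05; BH over a single test keeps it unchanged.
  g <- make_net("A", "L", isolated = sprintf("x%02d", 1:19))
  ext <- build_extended_network(g, "A", cutoff = 0.05, mode = "point")
  expect_identical(ext$linkers$p_adjusted, 0.05)
  expect_true(ext$linkers$accepted)
})

test_that("point mode reproduces the single hypergeometric term", {
  expect_equal(linker_pvalue(10, 4, 3, 2, mode = "point"),
               choose(4, 2) * choose(6, 1) / choose(10, 3))
  # on the boundary x = k the two modes coincide
  expect_equal(linker_pvalue(15, 6, 4, 4, mode = "point"),
               linker_pvalue(15, 6, 4, 4, mode = "tail"))
})
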