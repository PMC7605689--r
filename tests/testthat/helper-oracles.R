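# Fixture builders and independent oracles used across the suite.

# Build a named undirected graph from a flat vector of endpoint pairs:
# make_net("A","B", "B","C") gives A-B, B-C.
make_net <- function(..., isolated = character()) {
  v <- as.character(c(...))
  stopifnot(length(v) %% 2 == 0)
  el <- matrix(v, ncol = 2, byrow = TRUE)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (length(isolated) > 0) g <- igraph::add_vertices(g, length(isolated), name = isolated)
  g
}

random_named_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Exact hypergeometric tail by exhaustive enumeration: population 1..N with
# altered 1..A; fraction of all C(N,k) neighbor sets containing >= x altered.
hyper_tail_enum <- function(N, A, k, x) {
  sets <- utils::combn(N, k)
  hits <- colSums(sets <= A)   # members 1..A are the altered ones
  sum(hits >= x) / ncol(sets)
}

# Textbook BH step-up, written independently of stats::p.adjust.
bh_textbook <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# All set partitions of n labeled elements as membership vectors
# (restricted-growth-string enumeration); Bell(8) = 4140.
all_partitions <- function(n) {
  res <- list()
  recurse <- function(memb, next_id) {
    i <- length(memb) + 1L
    if (i > n) {
      res[[length(res) + 1L]] <<- memb
      return(invisible())
    }
    for (id in seq_len(next_id)) {
      recurse(c(memb, id), max(next_id, id + 1L))
    }
  }
  recurse(integer(), 1L)
  res
}

# Exhaustive maximum modularity over every partition of the node set.
max_modularity_exhaustive <- function(g) {
  nodes <- igraph::V(g)$name
  best <- -Inf
  for (memb in all_partitions(length(nodes))) {
    q <- netmodr::modularity_q(g, stats::setNames(memb, nodes))
    if (q > best) best <- q
  }
  best
}

# Two planted dense blocks joined sparsely; ground truth in $truth.
two_block_graph <- function(block = 8, seed = 1) {
  set.seed(seed)
  pm <- matrix(c(0.9, 0.05, 0.05, 0.9), 2)
  g <- igraph::sample_sbm(2 * block, pm, c(block, block))
  igraph::V(g)$name <- sprintf("v%02d", seq_len(2 * block))
  list(graph = g, truth = rep(1:2, each = block))
}
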