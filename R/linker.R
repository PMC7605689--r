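#' Candidate linker genes
#'
#' Candidate linkers are genes that carry no alteration themselves but are
#' direct neighbors of at least one altered gene. Altered genes are never
#' candidates, even when they neighbor other altered genes.
#'
#' @param network An [igraph::igraph] prior-knowledge network.
#' @param genes Altered genes: character vector, file path, or the tibble
#'   returned by [map_gene_list()].
#' @return Sorted character vector of candidate identifiers.
#' @export
find_candidate_linkers <- function(network, genes) {
  check_network(network)
  altered <- mapped_genes(network, genes)
  nbrs <- unique(unlist(
    lapply(igraph::adjacent_vertices(network, altered), function(vs) vs$name),
    use.names = FALSE
  ))
  sort(setdiff(nbrs, altered))
}

#' Hypergeometric linker p-value
#'
#' Probability that a node of degree `k`, drawing its neighbors uniformly
#' from a population of `N` genes of which `A` are altered, has at least
#' (`mode = "tail"`) or exactly (`mode = "point"`) `x` altered neighbors:
#' \deqn{\Pr(X \ge x) = \sum_{i=x}^{\min(k,A)}
#'   \frac{\binom{A}{i}\binom{N-A}{k-i}}{\binom{N}{k}}}{
#'   Pr(X >= x) = sum_i C(A,i) C(N-A,k-i) / C(N,k)}
#' The tail form is the p-value used for linker acceptance; the point form
#' reproduces the raw p-values of the original, pre-R implementation of the
#' algorithm (the two agree on the accepted set at the usual FDR cutoff but
#' not on raw values). Computation goes through [stats::phyper()] /
#' [stats::dhyper()], which work in log space and are stable for networks of
#' 1e5+ nodes. All arguments are vectorized and recycled.
#'
#' @param N Population size (number of possible neighbors).
#' @param A Number of altered genes in the population.
#' @param k Candidate degree (neighbors drawn).
#' @param x Observed altered-neighbor count.
#' @param mode `"tail"` for Pr(X >= x), `"point"` for Pr(X = x).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
#' @examples
#' linker_pvalue(10, 4, 3, 3)           # 4/120
#' linker_pvalue(10, 4, 3, 0)           # 1: whole support
linker_pvalue <- function(N, A, k, x, mode = c("tail", "point")) {
  mode <- match.arg(mode)
  n <- max(length(N), length(A), length(k), length(x))
  N <- rep_len(as.numeric(N), n); A <- rep_len(as.numeric(A), n)
  k <- rep_len(as.numeric(k), n); x <- rep_len(as.numeric(x), n)
  if (any(is.na(N) | is.na(A) | is.na(k) | is.na(x))) {
    abort("linker_pvalue() arguments must be non-missing.")
  }
  if (any(x < 0 | k < x | N < k | A > N | A < 0)) {
    abort("linker_pvalue() requires 0 <= x <= k <= N and 0 <= A <= N.")
  }
  if (mode == "tail") {
    # phyper(q, lower.tail = FALSE) is Pr(X > q); shift by one for Pr(X >= x)
    p <- phyper(x - 1, A, N - A, k, lower.tail = FALSE)
  } else {
    p <- dhyper(x, A, N - A, k)
  }
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sorted p-values are scaled by n/rank and made
#' monotone by a cumulative minimum from the largest rank down, clipped at 1.
#' Values are returned in input order. This is a thin, validated wrapper
#' around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in input order.
#' @export
adjust_pvalues <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Test candidate linkers and build the extended network
#'
#' Runs the linker-inference step of the module-discovery workflow: every
#' candidate linker (unaltered neighbor of an altered gene) is scored with
#' the hypergeometric tail test of [linker_pvalue()], p-values are BH
#' corrected across the candidate set, and candidates with adjusted p-value
#' less than *or equal to* `cutoff` are accepted. The extended network is
#' the subgraph induced on the mapped altered genes plus the accepted
#' linkers, with nodes left isolated by that restriction removed (they are
#' reported separately).
#'
#' The hypergeometric population is `N = vcount(network) - 1` (a candidate
#' cannot be its own neighbor) and `A` is the number of mapped altered
#' genes. Note that adding even an isolated node to the prior network
#' changes `N` and therefore every raw p-value.
#'
#' @inheritParams find_candidate_linkers
#' @param cutoff Acceptance threshold on the adjusted p-value, in (0, 1].
#'   The boundary is inclusive. Default 0.05.
#' @param mode Passed to [linker_pvalue()]; `"tail"` (default) or `"point"`.
#' @return An object of class `extended_network`: a list with
#' \describe{
#'   \item{graph}{the extended network as an [igraph::igraph];}
#'   \item{nodes}{tibble of retained nodes with columns `gene`, `role`
#'     (`"altered"` or `"linker"`);}
#'   \item{linkers}{tibble over *all* candidates, sorted by raw p-value:
#'     `gene`, `degree`, `altered_neighbors`, `p_raw`, `p_adjusted`,
#'     `accepted`;}
#'   \item{isolated_altered}{altered genes excluded because they have no
#'     edge within the extended node set;}
#'   \item{cutoff`, `mode}{the parameters used.}
#' }
#' @export
#' @examples
#' g <- as_interaction_network(data.frame(a = c("A", "L"), b = c("L", "B")))
#' ext <- build_extended_network(g, c("A", "B"), cutoff = 1)
#' tidy(ext)
build_extended_network <- function(network, genes, cutoff = 0.05,
                                   mode = c("tail", "point")) {
  check_network(network)
  mode <- match.arg(mode)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 1) {
    abort("`cutoff` must be a single probability in (0, 1].")
  }
  altered <- mapped_genes(network, genes)
  if (all(igraph::degree(network, altered) == 0L)) {
    abort("No altered gene has any edge in the network: no connected altered genes.")
  }

  candidates <- find_candidate_linkers(network, altered)
  if (length(candidates) > 0L) {
    deg <- igraph::degree(network, candidates)
    x <- vapply(
      igraph::adjacent_vertices(network, candidates),
      function(vs) sum(vs$name %in% altered), integer(1L)
    )
    p_raw <- linker_pvalue(
      N = igraph::vcount(network) - 1L, A = length(altered),
      k = deg, x = x, mode = mode
    )
    linkers <- tibble(
      gene = candidates,
      degree = as.integer(deg),
      altered_neighbors = as.integer(x),
      p_raw = p_raw,
      p_adjusted = adjust_pvalues(p_raw)
    )
    linkers$accepted <- linkers$p_adjusted <= cutoff
    linkers <- linkers[order(linkers$p_raw, linkers$gene), , drop = FALSE]
  } else {
    linkers <- tibble(
      gene = character(), degree = integer(), altered_neighbors = integer(),
      p_raw = numeric(), p_adjusted = numeric(), accepted = logical()
    )
  }

  keep <- c(altered, linkers$gene[linkers$accepted])
  sub <- igraph::induced_subgraph(network, keep)
  iso <- igraph::V(sub)$name[igraph::degree(sub) == 0L]
  sub <- igraph::delete_vertices(sub, iso)
  isolated_altered <- intersect(iso, altered)

  retained <- igraph::V(sub)$name
  nodes <- tibble(
    gene = retained,
    role = ifelse(retained %in% altered, "altered", "linker")
  )
  nodes <- nodes[order(nodes$role, nodes$gene), , drop = FALSE]

  structure(
    list(graph = sub, nodes = nodes, linkers = linkers,
         isolated_altered = isolated_altered,
         n_altered_mapped = length(altered),
         cutoff = cutoff, mode = mode),
    class = "extended_network"
  )
}

#' @export
print.extended_network <- function(x, ...) {
  cat("Extended network:",
      igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges\n")
  cat("  altered genes retained:", sum(x$nodes$role == "altered"),
      sprintf("(of %d mapped; %d isolated excluded)\n",
              x$n_altered_mapped, length(x$isolated_altered)))
  cat("  linkers accepted:", sum(x$linkers$accepted), "of",
      nrow(x$linkers), "candidates",
      sprintf("(%s test, FDR cutoff %g)\n", x$mode, x$cutoff))
  invisible(x)
}

#' @describeIn build_extended_network `tidy()` returns the per-candidate
#'   linker table.
#' @param x An `extended_network` object.
#' @param ... Unused.
#' @method tidy extended_network
#' @export
tidy.extended_network <- function(x, ...) x$linkers

#' @describeIn build_extended_network `glance()` returns a one-row summary.
#' @method glance extended_network
#' @export
glance.extended_network <- function(x, ...) {
  tibble(
    n_nodes = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    n_altered = sum(x$nodes$role == "altered"),
    n_isolated_altered = length(x$isolated_altered),
    n_candidates = nrow(x$linkers),
    n_linkers = sum(x$linkers$accepted),
    cutoff = x$cutoff,
    mode = x$mode
  )
}
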