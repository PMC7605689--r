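#' Size of the largest connected component induced by a gene set
#'
#' @param network An [igraph::igraph].
#' @param genes Genes to induce on (character vector of node names).
#' @return Integer node count of the largest component (1 when the induced
#'   subgraph has no internal edges but at least one node).
#' @export
lcc_size <- function(network, genes) {
  check_network(network)
  genes <- intersect(genes, igraph::V(network)$name)
  if (length(genes) == 0L) return(0L)
  sub <- igraph::induced_subgraph(network, genes)
  max(igraph::components(sub)$csize)
}

#' Global connectivity permutation test
#'
#' Asks whether the altered genes are more interconnected in the prior
#' network than a random gene set of the same size: the observed statistic
#' is the size of the largest connected component (LCC) of the subgraph
#' induced by the mapped altered genes; each null trial draws the same
#' number of genes uniformly without replacement from *all* network nodes
#' (the same frame the observed genes were mapped into) and records its
#' induced LCC. The empirical p-value uses the standard permutation
#' pseudocount, p = (r + 1) / (trials + 1) with r the number of trials whose
#' LCC equals or exceeds the observed one, so p is never 0.
#'
#' @param network The full prior-knowledge network.
#' @param genes Altered genes (vector, file path, or [map_gene_list()] tibble).
#' @param trials Number of null draws (default 1000).
#' @param seed Optional integer; when given the result is reproducible.
#' @return Object of class `lcc_test`: list with `observed`, `null_sizes`
#'   (length `trials`), `p_value`, `n_genes`, `trials`, `seed`.
#' @export
global_connectivity_test <- function(network, genes, trials = 1000, seed = NULL) {
  check_network(network)
  if (!is.numeric(trials) || trials < 1) abort("`trials` must be >= 1.")
  trials <- as.integer(trials)
  altered <- mapped_genes(network, genes)
  observed <- lcc_size(network, altered)
  nodes <- igraph::V(network)$name
  if (!is.null(seed)) set.seed(seed)
  null_sizes <- vapply(seq_len(trials), function(i) {
    lcc_size(network, sample(nodes, length(altered)))
  }, numeric(1L))
  r <- sum(null_sizes >= observed)
  structure(
    list(observed = observed, null_sizes = as.integer(null_sizes),
         p_value = (r + 1) / (trials + 1),
         n_genes = length(altered), trials = trials, seed = seed),
    class = "lcc_test"
  )
}

#' @export
print.lcc_test <- function(x, ...) {
  cat(sprintf(
    "Global connectivity test: observed LCC = %d of %d genes\n  null (n = %d trials): mean %.2f, max %d; empirical p = %.4g\n",
    x$observed, x$n_genes, x$trials, mean(x$null_sizes),
    max(x$null_sizes), x$p_value
  ))
  invisible(x)
}

#' Degree-preserving network rewiring
#'
#' Randomizes a network while keeping its size and every node's degree
#' fixed, via double edge swaps: two edges (a,b), (c,d) are replaced by
#' (a,d), (c,b) unless the swap would create a self-loop or duplicate edge.
#' `ceiling(swap_factor * ecount)` swaps are attempted. This is the null
#' ensemble for [modularity_significance()]. Interaction-type edge labels
#' are not carried over (partner identity is exactly what is randomized).
#'
#' @param network An [igraph::igraph] with at least 2 edges.
#' @param swap_factor Attempted swaps per edge (default 10, a common mixing
#'   heuristic).
#' @param seed Optional integer for reproducibility.
#' @return A rewired [igraph::igraph] with identical node set and degree
#'   sequence.
#' @export
rewire_network <- function(network, swap_factor = 10, seed = NULL) {
  check_network(network)
  if (igraph::ecount(network) < 2L) {
    abort("Rewiring needs at least 2 edges.")
  }
  if (!is.numeric(swap_factor) || swap_factor <= 0) {
    abort("`swap_factor` must be positive.")
  }
  if (!is.null(seed)) set.seed(seed)
  niter <- ceiling(swap_factor * igraph::ecount(network))
  if ("interaction" %in% igraph::edge_attr_names(network)) {
    network <- igraph::delete_edge_attr(network, "interaction")
  }
  igraph::rewire(network, igraph::keeping_degseq(loops = FALSE, niter = niter))
}

#' Modularity significance against a rewired null ensemble
#'
#' Detects communities on the observed network, then builds a null
#' distribution of modularity scores by repeatedly rewiring the network with
#' [rewire_network()] (same size, same degree for every gene, random
#' partners) and re-running community detection on each rewired copy — each
#' random network gets its own best partition. The observed modularity is
#' converted to a z-score against the null mean and standard deviation and
#' reported as a one-sided upper-tail normal p-value (high modularity =
#' more modular than degree-matched chance).
#'
#' If the null has zero variance (e.g. a triangle, which rewiring cannot
#' change), the z-score is `NA` and the p-value falls back to the empirical
#' fraction (r + 1) / (trials + 1) of null scores at or above the observed.
#'
#' @param network The network to assess (typically the extended network).
#' @param method Community-detection method, as in [detect_communities()].
#' @param trials Number of rewired null networks (default 100).
#' @param swap_factor Passed to [rewire_network()].
#' @param seed Optional master seed; per-trial seeds are derived from it.
#' @return Object of class `modularity_test`: list with `observed_q`,
#'   `null_q`, `null_mean`, `null_sd`, `z`, `p_value`, `partition` (the
#'   observed [detect_communities()] result), `trials`, `swap_factor`,
#'   `seed`.
#' @export
modularity_significance <- function(network,
                                    method = c("edge_betweenness", "leading_eigenvector"),
                                    trials = 100, swap_factor = 10, seed = NULL) {
  check_network(network)
  method <- match.arg(method)
  if (!is.numeric(trials) || trials < 2) {
    abort("`trials` must be >= 2 (a standard deviation needs two values).")
  }
  trials <- as.integer(trials)
  partition <- detect_communities(network, method)
  observed_q <- partition$modularity
  if (!is.null(seed)) set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, trials)
  null_q <- vapply(trial_seeds, function(s) {
    g <- rewire_network(network, swap_factor = swap_factor, seed = s)
    detect_communities(g, method)$modularity
  }, numeric(1L))
  null_mean <- mean(null_q)
  null_sd <- sd(null_q)
  if (null_sd > 0) {
    z <- (observed_q - null_mean) / null_sd
    p <- pnorm(z, lower.tail = FALSE)
  } else {
    warn("Null modularity distribution is degenerate (sd = 0); reporting the empirical fraction as p-value.")
    z <- NA_real_
    p <- (sum(null_q >= observed_q) + 1) / (trials + 1)
  }
  structure(
    list(observed_q = observed_q, null_q = null_q,
         null_mean = null_mean, null_sd = null_sd, z = z, p_value = p,
         partition = partition, trials = trials,
         swap_factor = swap_factor, seed = seed),
    class = "modularity_test"
  )
}

#' @export
print.modularity_test <- function(x, ...) {
  cat(sprintf(
    "Modularity significance: observed Q = %.4f\n  rewired null (n = %d): mean %.4f, sd %.4f\n  z = %s, one-sided p = %.4g\n",
    x$observed_q, x$trials, x$null_mean, x$null_sd,
    ifelse(is.na(x$z), "NA", sprintf("%.2f", x$z)), x$p_value
  ))
  invisible(x)
}

#' @describeIn global_connectivity_test `tidy()` returns the per-trial null
#'   LCC sizes.
#' @param x An `lcc_test`.
#' @param ... Unused.
#' @method tidy lcc_test
#' @export
tidy.lcc_test <- function(x, ...) {
  tibble(trial = seq_along(x$null_sizes), null_lcc = x$null_sizes)
}

#' @describeIn global_connectivity_test `glance()` returns a one-row summary.
#' @method glance lcc_test
#' @export
glance.lcc_test <- function(x, ...) {
  tibble(observed_lcc = x$observed, n_genes = x$n_genes,
         null_mean = mean(x$null_sizes), null_max = max(x$null_sizes),
         p_value = x$p_value, trials = x$trials)
}

#' @describeIn modularity_significance `tidy()` returns the per-trial null
#'   modularity scores.
#' @param x A `modularity_test`.
#' @param ... Unused.
#' @method tidy modularity_test
#' @export
tidy.modularity_test <- function(x, ...) {
  tibble(trial = seq_along(x$null_q), null_q = x$null_q)
}

#' @describeIn modularity_significance `glance()` returns a one-row summary.
#' @method glance modularity_test
#' @export
glance.modularity_test <- function(x, ...) {
  tibble(observed_q = x$observed_q, null_mean = x$null_mean,
         null_sd = x$null_sd, z = x$z, p_value = x$p_value,
         trials = x$trials)
}
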