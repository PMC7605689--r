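#' Newman modularity of a partition
#'
#' \deqn{Q = \sum_c (e_{cc} - a_c^2)}{Q = sum_c (e_cc - a_c^2)}
#' where \eqn{e_{cc}} is the fraction of edges with both endpoints in module
#' *c* and \eqn{a_c} the fraction of edge endpoints in *c*: the fraction of
#' within-module edges minus the fraction expected if edges were placed at
#' random with the same endpoint distribution. Exact for unweighted
#' undirected graphs; ranges over \[-0.5, 1\].
#'
#' @param network An [igraph::igraph] with at least one edge.
#' @param assignment Module membership: a named vector (names = genes) or a
#'   data frame with columns `gene` and `module`. Must cover every node.
#' @return Modularity Q as a single number.
#' @export
#' @examples
#' g <- as_interaction_network(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
#' modularity_q(g, c(A = 1, B = 1, C = 1))  # one module: exactly 0
modularity_q <- function(network, assignment) {
  check_network(network)
  if (is.data.frame(assignment)) {
    assignment <- stats::setNames(assignment$module, assignment$gene)
  }
  nodes <- igraph::V(network)$name
  if (is.null(names(assignment)) || !all(nodes %in% names(assignment))) {
    abort("`assignment` must cover every network node (named by gene).")
  }
  m <- igraph::ecount(network)
  if (m == 0L) abort("Modularity is undefined for an edgeless network.")
  memb <- assignment[nodes]
  el <- igraph::as_edgelist(network)
  same <- memb[el[, 1L]] == memb[el[, 2L]]
  ends <- c(memb[el[, 1L]], memb[el[, 2L]])
  a_c <- table(ends) / (2 * m)           # fraction of edge ends per module
  sum(same) / m - sum(a_c^2)
}

#' Partition a network into modules by community detection
#'
#' Two methods are offered. `"edge_betweenness"` is the Girvan-Newman
#' algorithm: edges of maximal betweenness are removed iteratively and the
#' partition (over the resulting dendrogram) that maximizes modularity is
#' returned. `"leading_eigenvector"` splits recursively along the leading
#' eigenvector of the modularity matrix, stopping when no split increases Q;
#' it is the practical choice for networks with thousands of nodes, and a
#' warning suggests it when edge betweenness is requested on a network of
#' more than 2000 nodes. Both are computed by igraph and are deterministic
#' for a given graph.
#'
#' Module ids are renumbered deterministically: decreasing module size, ties
#' broken by the lexicographically smallest member; ids are consecutive
#' integers starting at 1. An edgeless network yields singleton modules and
#' an `NA` modularity (Q is undefined without edges).
#'
#' @param network An [igraph::igraph]; disconnected components are
#'   partitioned jointly and fall into separate modules naturally.
#' @param method `"edge_betweenness"` (default) or `"leading_eigenvector"`.
#' @return An object of class `module_partition`: list with `membership`
#'   (tibble: `gene`, `module`), `modularity`, `method`, `n_modules`.
#' @export
#' @examples
#' # two triangles joined by a bridge split into the two triangles
#' g <- as_interaction_network(data.frame(
#'   a = c("a", "b", "c", "d", "e", "f", "a"),
#'   b = c("b", "c", "a", "e", "f", "d", "d")
#' ))
#' detect_communities(g)
detect_communities <- function(network,
                               method = c("edge_betweenness", "leading_eigenvector")) {
  check_network(network)
  method <- match.arg(method)
  if (igraph::vcount(network) == 0L) abort("Cannot partition an empty network.")

  if (igraph::ecount(network) == 0L) {
    memb <- stats::setNames(seq_len(igraph::vcount(network)),
                            igraph::V(network)$name)
    warn("Edgeless network: every node is its own module and Q is undefined.")
    return(new_module_partition(memb, NA_real_, method))
  }
  if (method == "edge_betweenness" && igraph::vcount(network) > 2000L) {
    warn(paste("Edge betweenness scales poorly beyond ~2000 nodes;",
               "consider method = \"leading_eigenvector\"."))
  }
  comm <- switch(method,
    edge_betweenness = igraph::cluster_edge_betweenness(
      network, weights = NULL, directed = FALSE
    ),
    leading_eigenvector = igraph::cluster_leading_eigen(network, weights = NULL)
  )
  memb <- igraph::membership(comm)
  new_module_partition(memb, modularity_q(network, memb), method)
}

# Canonical module numbering: by decreasing size, ties by smallest member.
new_module_partition <- function(membership, Q, method) {
  genes <- names(membership)
  sizes <- table(membership)
  smallest <- tapply(genes, membership, min)
  ord <- order(-as.integer(sizes), smallest)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  tab <- tibble(gene = genes,
                module = as.integer(relabel[as.character(membership)]))
  tab <- tab[order(tab$module, tab$gene), , drop = FALSE]
  structure(
    list(membership = tab, modularity = Q, method = method,
         n_modules = length(sizes)),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition (%s): %d modules over %d nodes, Q = %s\n",
              x$method, x$n_modules, nrow(x$membership),
              format(x$modularity, digits = 4)))
  sizes <- table(x$membership$module)
  cat("  module sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn detect_communities `tidy()` returns the gene-to-module table.
#' @param x A `module_partition`.
#' @param ... Unused.
#' @method tidy module_partition
#' @export
tidy.module_partition <- function(x, ...) x$membership

#' @describeIn detect_communities `glance()` returns a one-row summary with
#'   module count and modularity.
#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tibble(n_modules = x$n_modules, n_nodes = nrow(x$membership),
         modularity = x$modularity, method = x$method)
}
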