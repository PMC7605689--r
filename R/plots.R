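#' @importFrom ggplot2 ggplot aes geom_point geom_segment geom_histogram
#'   geom_vline geom_text labs theme_minimal theme element_blank
NULL

# Fruchterman-Reingold coordinates as a tibble keyed by gene.
graph_layout_tbl <- function(graph) {
  # layout is cosmetic; fix it so plots are reproducible, without
  # disturbing the caller's RNG stream
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(42L)
  xy <- igraph::layout_with_fr(graph)
  tibble(gene = igraph::V(graph)$name, x = xy[, 1L], y = xy[, 2L])
}

plot_network_tbl <- function(graph, node_tbl, colour_var) {
  lay <- graph_layout_tbl(graph)
  nodes <- merge(lay, node_tbl, by = "gene")
  el <- igraph::as_edgelist(graph)
  edges <- data.frame(
    x = lay$x[match(el[, 1L], lay$gene)], y = lay$y[match(el[, 1L], lay$gene)],
    xend = lay$x[match(el[, 2L], lay$gene)], yend = lay$y[match(el[, 2L], lay$gene)]
  )
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
                 colour = "grey70", linewidth = 0.3) +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, colour = .data[[colour_var]]),
               size = 3) +
    geom_text(data = nodes,
              aes(x = .data$x, y = .data$y, label = .data$gene),
              size = 2.3, vjust = -1.1) +
    theme_minimal() +
    theme(axis.title = element_blank(), axis.text = element_blank(),
          panel.grid = element_blank())
}

#' Plot an extended network coloured by node role
#'
#' @param object An `extended_network` from [build_extended_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot extended_network
#' @export
autoplot.extended_network <- function(object, ...) {
  plot_network_tbl(object$graph, object$nodes, "role") +
    labs(colour = "role", title = "Extended network: altered genes and accepted linkers")
}

#' Plot a module partition
#'
#' @param object A `module_partition` from [detect_communities()].
#' @param network The network the partition was computed on; required
#'   because the partition stores membership only.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot module_partition
#' @export
autoplot.module_partition <- function(object, network, ...) {
  check_network(network)
  memb <- object$membership
  memb$module <- factor(memb$module)
  plot_network_tbl(network, memb, "module") +
    labs(colour = "module",
         title = sprintf("Modules (%s), Q = %.3f", object$method, object$modularity))
}

#' Plot the null distribution of a connectivity test
#'
#' Histogram of the null largest-connected-component sizes with the
#' observed value marked.
#'
#' @param object An `lcc_test` from [global_connectivity_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lcc_test
#' @export
autoplot.lcc_test <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$null_lcc)) +
    geom_histogram(binwidth = 1, fill = "grey60", colour = "white") +
    geom_vline(xintercept = object$observed, colour = "firebrick", linewidth = 0.8) +
    labs(x = "null LCC size", y = "trials",
         title = sprintf("Observed LCC = %d, empirical p = %.3g",
                         object$observed, object$p_value)) +
    theme_minimal()
}

#' Plot the rewired-null modularity distribution
#'
#' @param object A `modularity_test` from [modularity_significance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot modularity_test
#' @export
autoplot.modularity_test <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$null_q)) +
    geom_histogram(bins = 30, fill = "grey60", colour = "white") +
    geom_vline(xintercept = object$observed_q, colour = "firebrick", linewidth = 0.8) +
    labs(x = "null modularity Q", y = "trials",
         title = sprintf("Observed Q = %.3f, z = %s, p = %.3g",
                         object$observed_q,
                         ifelse(is.na(object$z), "NA", sprintf("%.2f", object$z)),
                         object$p_value)) +
    theme_minimal()
}
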