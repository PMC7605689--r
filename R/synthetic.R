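#' Configuration for the planted-module benchmark generator
#'
#' Describes a stochastic-block-model network with dense planted modules
#' embedded in a sparse background, plus an altered-gene list with
#' controlled signal. The defaults define the package's reference benchmark:
#' three modules of 12 genes (intra-module edge probability 0.6), 40
#' background genes, all other edges at probability 0.02, 70% of each
#' module's genes altered, and 5 altered background genes. Background nodes
#' stand in for the bulk of a prior network that carries no signal, which is
#' what gives the hypergeometric linker test a non-trivial population.
#'
#' The unaltered module members are the "withheld linkers": genes a perfect
#' analysis would recover as linkers even though they are absent from the
#' altered list.
#'
#' @param n_modules Number of planted modules.
#' @param module_sizes Integer vector of module sizes (recycled to
#'   `n_modules`); every size must be >= 2.
#' @param p_intra Edge probability within a module.
#' @param p_inter Edge probability between two different modules.
#' @param background_nodes Number of background nodes.
#' @param p_background Edge probability for any pair involving a background
#'   node.
#' @param altered_fraction Fraction of each module's nodes put on the
#'   altered list.
#' @param altered_background Number of background nodes put on the altered
#'   list.
#' @param seed Integer seed making the generated instance reproducible.
#' @return A `planted_config` list, validated.
#' @export
planted_config <- function(n_modules = 3, module_sizes = 12,
                           p_intra = 0.6, p_inter = 0.02,
                           background_nodes = 40, p_background = 0.02,
                           altered_fraction = 0.7, altered_background = 5,
                           seed = 1) {
  cfg <- list(
    n_modules = as.integer(n_modules),
    module_sizes = rep_len(as.integer(module_sizes), n_modules),
    p_intra = p_intra, p_inter = p_inter,
    background_nodes = as.integer(background_nodes),
    p_background = p_background,
    altered_fraction = altered_fraction,
    altered_background = as.integer(altered_background),
    seed = as.integer(seed)
  )
  if (cfg$n_modules < 1L) abort("`n_modules` must be >= 1.")
  if (any(cfg$module_sizes < 2L)) abort("Every module size must be >= 2.")
  if (!(p_inter >= 0 && p_inter < p_intra && p_intra <= 1)) {
    abort("Need 0 <= p_inter < p_intra <= 1.")
  }
  if (p_background < 0 || p_background > 1) abort("`p_background` must be in [0, 1].")
  if (altered_fraction <= 0 || altered_fraction > 1) {
    abort("`altered_fraction` must be in (0, 1].")
  }
  if (cfg$altered_background < 0 || cfg$altered_background > cfg$background_nodes) {
    abort("`altered_background` must be between 0 and `background_nodes`.")
  }
  structure(cfg, class = "planted_config")
}

#' Generate a planted-module network with an altered-gene list
#'
#' Draws a stochastic block model: blocks are the planted modules plus one
#' background block; edges appear independently with probability `p_intra`
#' within a module, `p_inter` between modules, and `p_background` for any
#' pair touching the background. The altered list contains
#' `round(altered_fraction * size)` random members of each module plus
#' `altered_background` random background nodes. Withheld linkers are the
#' unaltered module members that have at least one altered neighbor (and
#' are therefore valid linker candidates).
#'
#' @param config A [planted_config()].
#' @return Object of class `planted_truth`: list with `network` (igraph),
#'   `true_modules` (tibble `gene`, `module`; background nodes carry `NA`),
#'   `altered` (character), `withheld_linkers` (character), `config`.
#' @export
#' @examples
#' truth <- generate_planted(planted_config(seed = 7))
#' length(truth$altered)
generate_planted <- function(config = planted_config()) {
  if (!inherits(config, "planted_config")) {
    config <- do.call(planted_config, as.list(config))
  }
  set.seed(config$seed)
  sizes <- config$module_sizes
  nm <- config$n_modules
  blocks <- c(sizes, config$background_nodes)
  nb <- length(blocks)
  pm <- matrix(config$p_inter, nb, nb)
  diag(pm)[seq_len(nm)] <- config$p_intra
  if (config$background_nodes > 0L) {
    pm[nb, ] <- config$p_background
    pm[, nb] <- config$p_background
  }
  g <- igraph::sample_sbm(sum(blocks), pref.matrix = pm, block.sizes = blocks)
  module_of <- rep(c(seq_len(nm), NA_integer_), blocks)
  names_g <- character(sum(blocks))
  in_module <- !is.na(module_of)
  names_g[in_module] <- sprintf("M%d_%02d", module_of[in_module],
                                unlist(lapply(sizes, seq_len)))
  if (config$background_nodes > 0L) {
    names_g[!in_module] <- sprintf("BG%03d", seq_len(config$background_nodes))
  }
  igraph::V(g)$name <- names_g

  altered <- unlist(lapply(seq_len(nm), function(m) {
    members <- names_g[which(module_of == m)]
    sample(members, round(config$altered_fraction * length(members)))
  }), use.names = FALSE)
  if (config$altered_background > 0L) {
    bg <- names_g[is.na(module_of)]
    altered <- c(altered, sample(bg, config$altered_background))
  }
  altered <- sort(altered)

  unaltered_members <- setdiff(names_g[!is.na(module_of)], altered)
  has_alt_nbr <- vapply(unaltered_members, function(v) {
    any(igraph::neighbors(g, v)$name %in% altered)
  }, logical(1L))
  withheld <- sort(unaltered_members[has_alt_nbr])

  structure(
    list(network = g,
         true_modules = tibble(gene = names_g, module = module_of),
         altered = altered,
         withheld_linkers = withheld,
         config = config),
    class = "planted_truth"
  )
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf(
    "Planted benchmark: %d modules (sizes %s) + %d background nodes, %d edges\n  altered genes: %d; withheld linkers: %d (seed %d)\n",
    x$config$n_modules, paste(x$config$module_sizes, collapse = "/"),
    x$config$background_nodes, igraph::ecount(x$network),
    length(x$altered), length(x$withheld_linkers), x$config$seed
  ))
  invisible(x)
}

#' Score module and linker recovery against a planted truth
#'
#' Compares a pipeline result with the ground truth of
#' [generate_planted()]. Module recovery is the adjusted Rand index between
#' the planted and inferred assignments, restricted to true module members
#' that made it into the partitioned (extended) network — background nodes
#' and dropped genes are excluded so the index measures recovery of the
#' planted structure, not of noise. Linker recovery is (a) recall, the
#' fraction of withheld linkers accepted, and (b) the count of accepted
#' linkers among background nodes (false positives).
#'
#' @param truth A `planted_truth`.
#' @param partition A `module_partition` computed on (a subgraph of)
#'   `truth$network`, or a data frame with columns `gene` and `module`.
#' @param linkers The linker table of [build_extended_network()] (or an
#'   `extended_network`, from which it is taken).
#' @return One-row tibble: `ari`, `linker_recall`, `linker_fp`,
#'   `n_members_partitioned`, `n_withheld`.
#' @export
score_recovery <- function(truth, partition, linkers) {
  if (!inherits(truth, "planted_truth")) abort("`truth` must come from generate_planted().")
  if (inherits(partition, "module_partition")) {
    inferred <- partition$membership
  } else if (is.data.frame(partition) && all(c("gene", "module") %in% names(partition))) {
    inferred <- partition
  } else {
    abort("`partition` must come from detect_communities() or have columns gene, module.")
  }
  if (inherits(linkers, "extended_network")) linkers <- linkers$linkers
  if (!any(inferred$gene %in% truth$true_modules$gene)) {
    abort("Partition and truth share no nodes.")
  }
  members <- truth$true_modules[!is.na(truth$true_modules$module), , drop = FALSE]
  common <- intersect(members$gene, inferred$gene)
  ari <- if (length(common) < 2L) NA_real_ else {
    mclust::adjustedRandIndex(
      members$module[match(common, members$gene)],
      inferred$module[match(common, inferred$gene)]
    )
  }
  accepted <- linkers$gene[linkers$accepted]
  n_wh <- length(truth$withheld_linkers)
  recall <- if (n_wh == 0L) NA_real_ else {
    mean(truth$withheld_linkers %in% accepted)
  }
  bg <- truth$true_modules$gene[is.na(truth$true_modules$module)]
  tibble(
    ari = ari,
    linker_recall = recall,
    linker_fp = sum(accepted %in% bg),
    n_members_partitioned = length(common),
    n_withheld = n_wh
  )
}
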