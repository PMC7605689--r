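#' Run the full module-discovery pipeline and write a results bundle
#'
#' One-call orchestration: load the network and altered-gene list, test
#' candidate linkers ([build_extended_network()]), partition the extended
#' network ([detect_communities()]), run both significance tests
#' ([global_connectivity_test()] on the full network,
#' [modularity_significance()] on the extended network), and write all
#' results plus a reproducibility manifest to `output_dir`.
#'
#' Files written: `linker_table.tsv`, `module_table.tsv` (gene, module,
#' role), `extended_network.sif` and `.graphml`, `isolated_altered.txt`,
#' `significance.tsv` and `significance.json`, `manifest.json` (parameters,
#' seed, package/R versions, md5 checksums of the input files). Runs with
#' the same inputs and seed produce byte-identical bundles.
#'
#' @param network Path to a SIF/edge-table file, or an [igraph::igraph].
#' @param genes Path to a gene-list file, or a character vector.
#' @param output_dir Directory for the bundle; must not exist or be empty
#'   unless `force = TRUE`.
#' @param cutoff FDR cutoff for linker acceptance (inclusive; default 0.05).
#' @param linker_mode `"tail"` (default) or `"point"`; see [linker_pvalue()].
#' @param community_method `"edge_betweenness"` or `"leading_eigenvector"`.
#' @param lcc_trials Trials for the connectivity test (default 1000).
#' @param mod_trials Rewired networks for the modularity null (default 100).
#' @param swap_factor Attempted swaps per edge when rewiring (default 10).
#' @param seed Master seed; both permutation tests derive from it.
#' @param force Overwrite a non-empty `output_dir`.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with `extended`, `partition`, `lcc`,
#'   `modularity`, `manifest`, `output_dir`.
#' @export
run_pipeline <- function(network, genes, output_dir,
                         cutoff = 0.05, linker_mode = c("tail", "point"),
                         community_method = c("edge_betweenness", "leading_eigenvector"),
                         lcc_trials = 1000, mod_trials = 100, swap_factor = 10,
                         seed = 1, force = FALSE, quiet = FALSE) {
  linker_mode <- match.arg(linker_mode)
  community_method <- match.arg(community_method)
  say <- function(...) if (!quiet) inform(sprintf(...))

  if (dir.exists(output_dir) && length(dir(output_dir, all.files = TRUE, no.. = TRUE)) > 0L && !force) {
    abort(sprintf("Output directory '%s' is not empty (use force = TRUE to overwrite).", output_dir))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  checksums <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }

  net <- stage("load-network", {
    if (is.character(network)) {
      checksums$network <- unname(tools::md5sum(network))
      if (grepl("\\.sif$", network, ignore.case = TRUE)) {
        read_sif(network)
      } else {
        read_edge_table(network)
      }
    } else {
      check_network(network)
    }
  })
  gene_input <- stage("load-genes", {
    if (is.character(genes) && length(genes) == 1L && file.exists(genes)) {
      checksums$genes <- unname(tools::md5sum(genes))
      read_gene_list(genes)
    } else genes
  })
  mapping <- stage("map-genes", map_gene_list(net, gene_input))
  say("network: %d nodes, %d edges; altered genes mapped: %d of %d",
      igraph::vcount(net), igraph::ecount(net),
      sum(mapping$in_network), nrow(mapping))

  ext <- stage("linker-test",
    build_extended_network(net, mapping, cutoff = cutoff, mode = linker_mode))
  say("linkers: %d candidates tested, %d accepted (FDR <= %g); extended network %d nodes / %d edges",
      nrow(ext$linkers), sum(ext$linkers$accepted), cutoff,
      igraph::vcount(ext$graph), igraph::ecount(ext$graph))

  partition <- stage("community-detection",
    detect_communities(ext$graph, community_method))
  say("modules: %d found, Q = %.4f (%s)", partition$n_modules,
      partition$modularity, community_method)

  lcc <- stage("connectivity-test",
    global_connectivity_test(net, mapping, trials = lcc_trials, seed = seed))
  mod <- stage("modularity-test",
    modularity_significance(ext$graph, method = community_method,
                            trials = mod_trials, swap_factor = swap_factor,
                            seed = seed + 1L))
  say("significance: LCC %d, p = %.4g; Q z = %s, p = %.4g",
      lcc$observed, lcc$p_value,
      ifelse(is.na(mod$z), "NA", sprintf("%.2f", mod$z)), mod$p_value)

  module_table <- merge(partition$membership, ext$nodes, by = "gene")
  module_table <- module_table[order(module_table$module, module_table$gene), , drop = FALSE]

  stage("write-bundle", {
    write_tsv_file(ext$linkers, file.path(output_dir, "linker_table.tsv"))
    write_tsv_file(module_table, file.path(output_dir, "module_table.tsv"))
    write_network(ext$graph, file.path(output_dir, "extended_network.sif"), "sif")
    write_network(ext$graph, file.path(output_dir, "extended_network.graphml"), "graphml")
    write_lines_file(ext$isolated_altered, file.path(output_dir, "isolated_altered.txt"))
    sig <- tibble(
      statistic = c("observed_lcc", "lcc_null_mean", "lcc_null_sd", "lcc_p",
                    "observed_q", "q_null_mean", "q_null_sd", "q_z", "q_p"),
      value = c(lcc$observed, mean(lcc$null_sizes), sd(lcc$null_sizes),
                lcc$p_value, mod$observed_q, mod$null_mean, mod$null_sd,
                mod$z, mod$p_value)
    )
    write_tsv_file(sig, file.path(output_dir, "significance.tsv"))
    sig_json <- list(
      lcc = list(observed = lcc$observed, trials = lcc$trials,
                 null_sizes = lcc$null_sizes, p_value = lcc$p_value),
      modularity = list(observed_q = mod$observed_q, trials = mod$trials,
                        null_mean = mod$null_mean, null_sd = mod$null_sd,
                        z = mod$z, p_value = mod$p_value,
                        null_q = mod$null_q)
    )
    write_json_file(sig_json, file.path(output_dir, "significance.json"))
  })

  manifest <- list(
    parameters = list(
      network = if (is.character(network)) network else "<igraph object>",
      genes = if (is.character(genes) && length(genes) == 1L && file.exists(genes)) genes else "<in-memory list>",
      cutoff = cutoff, linker_mode = linker_mode,
      community_method = community_method, lcc_trials = lcc_trials,
      mod_trials = mod_trials, swap_factor = swap_factor, seed = seed
    ),
    input_md5 = checksums,
    counts = list(
      network_nodes = igraph::vcount(net), network_edges = igraph::ecount(net),
      genes_requested = nrow(mapping), genes_mapped = sum(mapping$in_network),
      candidates = nrow(ext$linkers), linkers_accepted = sum(ext$linkers$accepted),
      extended_nodes = igraph::vcount(ext$graph), modules = partition$n_modules
    ),
    versions = list(netmodr = as.character(packageVersion("netmodr")),
                    r = R.version.string,
                    igraph = as.character(packageVersion("igraph")))
  )
  write_json_file(manifest, file.path(output_dir, "manifest.json"))

  invisible(list(extended = ext, partition = partition, lcc = lcc,
                 modularity = mod, manifest = manifest,
                 output_dir = output_dir))
}

# LF line endings and fixed number formatting regardless of platform/locale,
# so identical runs are byte-identical.
write_tsv_file <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE))
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(df), sep = "\t")))
  if (nrow(df) == 0L) lines <- lines[1L]
  write_lines_file(lines, path)
}

write_lines_file <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

write_json_file <- function(x, path) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  write_lines_file(jsonlite::prettify(json, indent = 2), path)
}
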