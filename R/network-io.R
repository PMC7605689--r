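#' Read an interaction network from a SIF file
#'
#' SIF (simple interaction format) is the three-column text format used by
#' Cytoscape and Pathway Commons: `source  interaction-type  target`, one
#' interaction per line, delimited by tabs or runs of spaces. Lines of the
#' form `A pp A` (self-interactions) contribute the node but no edge.
#'
#' The returned network is normalized: undirected, no self-loops, each
#' unordered node pair present at most once. When duplicate edges carry
#' conflicting interaction-type labels the first-seen label is kept and a
#' message reports the conflict (the discovery algorithm never uses labels).
#' Identifiers are stripped of surrounding whitespace but otherwise preserved
#' byte-for-byte; in particular case is never folded, so identifiers must be
#' pre-harmonized by the user.
#'
#' @param path Path to a SIF file.
#' @return An [igraph::igraph] object: undirected, simple, with vertex
#'   attribute `name` and edge attribute `interaction`.
#' @seealso [read_edge_table()], [write_network()]
#' @export
#' @examples
#' sif <- tempfile(fileext = ".sif")
#' writeLines(c("TP53\tpp\tMDM2", "MDM2\tpp\tTP53", "TP53\tpp\tTP53"), sif)
#' g <- read_sif(sif)
#' igraph::ecount(g)  # 1: reciprocal rows merge, self-loop dropped
read_sif <- function(path) {
  lines <- read_text_lines(path)
  fields <- strsplit(trimws(lines$text), "[\t ]+")
  n_fields <- lengths(fields)
  bad <- which(n_fields != 3L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed SIF line %d in '%s': expected 3 fields, found %d.",
      lines$line[bad[1L]], path, n_fields[bad[1L]]
    ))
  }
  mat <- do.call(rbind, fields)
  build_network(source = mat[, 1L], target = mat[, 3L], label = mat[, 2L])
}

#' Read an interaction network from a two- or three-column edge table
#'
#' Tab-separated edge list with columns `source<TAB>target` (unlabeled edges)
#' or `source<TAB>type<TAB>target`. All data lines must have the same number
#' of columns. Normalization is identical to [read_sif()].
#'
#' @param path Path to a TSV file.
#' @param has_header If `TRUE`, the first line is discarded.
#' @return An undirected simple [igraph::igraph]; the `interaction` edge
#'   attribute is present only for three-column input.
#' @export
read_edge_table <- function(path, has_header = FALSE) {
  lines <- read_text_lines(path)
  if (has_header) {
    lines$text <- lines$text[-1L]
    lines$line <- lines$line[-1L]
    if (length(lines$text) == 0L) {
      abort(sprintf("Edge table '%s' has a header but no data lines.", path))
    }
  }
  fields <- strsplit(trimws(lines$text), "\t")
  n_fields <- lengths(fields)
  if (!all(n_fields %in% c(2L, 3L))) {
    bad <- which(!n_fields %in% c(2L, 3L))[1L]
    abort(sprintf(
      "Malformed edge-table line %d in '%s': expected 2 or 3 columns, found %d.",
      lines$line[bad], path, n_fields[bad]
    ))
  }
  if (length(unique(n_fields)) > 1L) {
    bad <- which(n_fields != n_fields[1L])[1L]
    abort(sprintf(
      "Inconsistent column counts in '%s': line %d has %d columns, line %d has %d.",
      path, lines$line[1L], n_fields[1L], lines$line[bad], n_fields[bad]
    ))
  }
  mat <- do.call(rbind, fields)
  if (ncol(mat) == 2L) {
    build_network(source = mat[, 1L], target = mat[, 2L], label = NULL)
  } else {
    build_network(source = mat[, 1L], target = mat[, 3L], label = mat[, 2L])
  }
}

#' Coerce an edge data frame to a normalized interaction network
#'
#' Programmatic counterpart of the file readers: takes a data frame whose
#' first and last columns are interaction partners (with an optional type
#' column in between) and applies the same normalization contract.
#'
#' @param edges A data frame with 2 or 3 character columns.
#' @return An undirected simple [igraph::igraph].
#' @export
as_interaction_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!ncol(edges) %in% c(2L, 3L)) {
    abort("`edges` must have 2 (source, target) or 3 (source, type, target) columns.")
  }
  if (nrow(edges) == 0L) abort("`edges` has no rows.")
  if (ncol(edges) == 2L) {
    build_network(as.character(edges[[1L]]), as.character(edges[[2L]]), NULL)
  } else {
    build_network(as.character(edges[[1L]]), as.character(edges[[3L]]),
                  as.character(edges[[2L]]))
  }
}

# Shared normalization: whitespace-stripped ids, undirected, self-loops
# dropped, duplicate unordered pairs merged keeping the first-seen label.
# Nodes appearing only in dropped self-loops are retained as isolated nodes.
build_network <- function(source, target, label = NULL) {
  source <- trimws(source)
  target <- trimws(target)
  if (any(source == "" | target == "")) {
    abort("Empty node identifier after whitespace stripping.")
  }
  loop <- source == target
  nodes <- unique(c(source, target))
  src <- source[!loop]
  tgt <- target[!loop]
  lab <- if (!is.null(label)) trimws(label)[!loop]
  # canonical unordered key
  key <- ifelse(src <= tgt, paste(src, tgt, sep = "\r"), paste(tgt, src, sep = "\r"))
  first <- !duplicated(key)
  if (!is.null(lab) && anyDuplicated(key)) {
    kept <- lab[first][match(key, key[first])]
    n_conflict <- sum(lab != kept)
    if (n_conflict > 0L) {
      inform(sprintf(
        "%d duplicate edge(s) had conflicting interaction labels; first-seen label kept.",
        n_conflict
      ))
    }
  }
  el <- data.frame(from = src[first], to = tgt[first], stringsAsFactors = FALSE)
  if (!is.null(lab)) el$interaction <- lab[first]
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

read_text_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw)))
  if (length(keep) == 0L) abort(sprintf("File '%s' is empty.", path))
  list(text = raw[keep], line = keep)
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines are ignored, surrounding whitespace
#' stripped, duplicates collapsed with a message reporting how many.
#'
#' @param path Path to a text file.
#' @return Character vector of unique identifiers in first-seen order.
#' @export
read_gene_list <- function(path) {
  lines <- read_text_lines(path)
  ids <- trimws(lines$text)
  dup <- sum(duplicated(ids))
  if (dup > 0L) {
    inform(sprintf("Gene list '%s': %d duplicate identifier(s) collapsed.", path, dup))
  }
  unique(ids)
}

#' Map an altered-gene list onto a network
#'
#' Partitions the requested identifiers into those present in the network
#' node set (`mapped`) and those absent (`unmapped`). Matching is exact
#' string equality after whitespace stripping; case is not folded.
#'
#' @param network An [igraph::igraph] with named vertices.
#' @param genes Character vector of identifiers, or a path to a file read
#'   with [read_gene_list()].
#' @return A tibble with columns `gene` and `in_network` (logical), one row
#'   per unique requested identifier, in input order. Errors if no gene maps.
#' @export
#' @examples
#' g <- as_interaction_network(data.frame(a = c("A", "B"), b = c("B", "C")))
#' map_gene_list(g, c("A", "B", "Z"))
map_gene_list <- function(network, genes) {
  check_network(network)
  if (is.character(genes) && length(genes) == 1L && file.exists(genes)) {
    genes <- read_gene_list(genes)
  }
  if (!is.character(genes)) abort("`genes` must be a character vector or a file path.")
  genes <- unique(trimws(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) abort("Empty gene list.")
  mapping <- tibble(gene = genes,
                    in_network = genes %in% igraph::V(network)$name)
  if (!any(mapping$in_network)) {
    abort("None of the requested genes map into the network; nothing to analyze.")
  }
  mapping
}

# Resolve a `genes` argument (vector, file path, or map_gene_list() tibble)
# to the mapped subset, warning about unmapped identifiers.
mapped_genes <- function(network, genes, quiet = FALSE) {
  if (is.data.frame(genes)) {
    if (!all(c("gene", "in_network") %in% names(genes))) {
      abort("A data-frame `genes` must have columns `gene` and `in_network`.")
    }
    mapping <- genes
    mapping$in_network <- mapping$gene %in% igraph::V(network)$name
    quiet <- TRUE  # an explicit map_gene_list() result already carries this
  } else {
    mapping <- map_gene_list(network, genes)
  }
  n_un <- sum(!mapping$in_network)
  if (n_un > 0L && !quiet) {
    warn(sprintf("%d of %d altered gene(s) not present in the network were dropped.",
                 n_un, nrow(mapping)))
  }
  mapped <- mapping$gene[mapping$in_network]
  if (length(mapped) == 0L) {
    abort("None of the requested genes map into the network; nothing to analyze.")
  }
  mapped
}

#' Write an interaction network to disk
#'
#' Supported formats: `"sif"` (three columns; unlabeled edges get the
#' placeholder type `"interacts"`), `"edge-table"` (TSV, 3 columns when the
#' network carries labels, else 2), and `"graphml"`. SIF and edge-table are
#' edge lists and therefore cannot represent isolated nodes, which are
#' dropped with a warning; GraphML retains them. Reloading the written file
#' reproduces the node and edge sets (modulo that caveat).
#'
#' @param network An [igraph::igraph] with named vertices.
#' @param path Output file path.
#' @param format One of `"sif"`, `"edge-table"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("sif", "edge-table", "graphml")) {
  check_network(network)
  if (!is.character(format) || length(format) < 1L ||
      !format[1L] %in% c("sif", "edge-table", "graphml")) {
    abort(sprintf("Unknown network format '%s'.", paste(format[1L], collapse = "")))
  }
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
    return(invisible(path))
  }
  n_iso <- sum(igraph::degree(network) == 0L)
  if (n_iso > 0L) {
    warn(sprintf("%d isolated node(s) cannot be represented in %s output and were dropped.",
                 n_iso, format))
  }
  el <- igraph::as_edgelist(network)
  lab <- igraph::edge_attr(network, "interaction")
  if (format == "sif") {
    if (is.null(lab)) lab <- rep("interacts", nrow(el))
    lab[is.na(lab) | lab == ""] <- "interacts"
    out <- paste(el[, 1L], lab, el[, 2L], sep = "\t")
  } else if (is.null(lab)) {
    out <- paste(el[, 1L], el[, 2L], sep = "\t")
  } else {
    lab[is.na(lab)] <- "interacts"
    out <- paste(el[, 1L], lab, el[, 2L], sep = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

check_network <- function(network) {
  if (!igraph::is_igraph(network)) {
    abort("`network` must be an igraph object (see read_sif()).")
  }
  if (is.null(igraph::V(network)$name)) {
    abort("`network` vertices must be named with gene identifiers.")
  }
  invisible(network)
}
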