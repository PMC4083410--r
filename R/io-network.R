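#' Build an interaction network from an edge table
#'
#' The protein functional-interaction network is undirected and
#' unweighted: self-loops are discarded (their count is recorded) and
#' duplicate edges — including reversed duplicates — are collapsed.
#'
#' @param edges A data frame whose first two columns are the edge
#'   endpoints (gene identifiers).
#' @param alias Optional alias table (see [apply_gene_alias()]).
#' @return An undirected [igraph::igraph] with vertex `name`s set to
#'   normalized gene IDs; attributes `"n_self_loops"` and
#'   `"n_duplicate_edges"` record what was dropped.
#' @export
as_interaction_network <- function(edges, alias = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  a <- apply_gene_alias(edges[[1]], alias)
  b <- apply_gene_alias(edges[[2]], alias)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  loops <- a == b
  n_loops <- sum(loops)
  a <- a[!loops]; b <- b[!loops]
  # canonical order so {x,y} and {y,x} deduplicate together
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[!dup], to = hi[!dup]),
    directed = FALSE
  )
  igraph::graph_attr(g, "n_self_loops") <- n_loops
  igraph::graph_attr(g, "n_duplicate_edges") <- sum(dup)
  g
}

#' Load an interaction network from a TSV or SIF edge list
#'
#' Accepts a two-column tab-delimited edge list (with or without a header
#' line) or a three-column SIF file (`node relation node`). Lines with
#' fewer than two fields raise an error naming the line number.
#'
#' @param path Path to the edge list.
#' @param format `"auto"` (default, decided by column count), `"tsv"` or
#'   `"sif"`.
#' @param alias Optional alias table.
#' @return An undirected igraph; see [as_interaction_network()].
#' @export
load_network <- function(path, format = c("auto", "tsv", "sif"), alias = NULL) {
  format <- match.arg(format)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(as_interaction_network(data.frame(a = character(), b = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2)
  if (length(bad) > 0) {
    abort(sprintf("%s: unreadable edge at line %d (fewer than 2 fields)", path, bad[1]))
  }
  if (format == "auto") {
    format <- if (all(nf >= 3)) "sif" else "tsv"
  }
  a <- map_chr(fields, 1)
  b <- if (format == "sif") map_chr(fields, 3) else map_chr(fields, 2)
  # drop a header line if the first row looks like column labels
  if (tolower(a[1]) %in% c("from", "source", "gene1", "genea", "node1") ||
      tolower(b[1]) %in% c("to", "target", "gene2", "geneb", "node2")) {
    a <- a[-1]; b <- b[-1]
  }
  as_interaction_network(data.frame(a = a, b = b), alias = alias)
}

#' Write an interaction network as a two-column TSV edge list
#'
#' @param network An igraph network.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network)
  readr::write_tsv(tibble(from = el[, 1], to = el[, 2]), path)
  invisible(path)
}

#' Tidy edge table of an interaction network
#'
#' @param network An igraph network.
#' @return A tibble with columns `from` and `to`, one row per undirected
#'   edge (stored once, endpoints in lexicographic order).
#' @export
network_edges <- function(network) {
  el <- igraph::as_edgelist(network)
  tibble(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2])) %>%
    arrange(.data$from, .data$to)
}

# restrict a gene set to network vertices; count the unmapped
map_to_network <- function(network, genes, what = "genes") {
  genes <- unique(normalize_gene_id(genes))
  genes <- genes[!is.na(genes)]
  present <- genes[genes %in% igraph::V(network)$name]
  attr(present, "n_unmapped") <- length(genes) - length(present)
  present
}
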