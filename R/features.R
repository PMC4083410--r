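#' Common-neighbor (Jaccard) score between two genes
#'
#' The proportion of neighbors shared by two genes:
#' `|N_A intersect N_B| / |N_A union N_B|`, where `N_X` is the neighbor
#' set of gene X. Symmetric; defined as 0 when both neighbor sets are
#' empty (no evidence of association).
#'
#' @param network An igraph interaction network.
#' @param gene_a,gene_b Gene IDs; both must be network nodes.
#' @return A number in `[0, 1]`.
#' @export
common_neighbor_score <- function(network, gene_a, gene_b) {
  gene_a <- normalize_gene_id(gene_a)
  gene_b <- normalize_gene_id(gene_b)
  nodes <- igraph::V(network)$name
  if (!gene_a %in% nodes || !gene_b %in% nodes) {
    abort("both genes must be present in the network")
  }
  na <- igraph::neighbors(network, gene_a)$name
  nb <- igraph::neighbors(network, gene_b)$name
  u <- length(union(na, nb))
  if (u == 0) return(0)
  length(intersect(na, nb)) / u
}

#' Network feature matrix for drug-target prediction
#'
#' One row per candidate gene (the drug-target universe mapped to the
#' network) with `3 + N` features: the number of the disease's GWAS genes
#' that are direct neighbors, the gene's network degree, the number of
#' GWAS genes at shortest distance exactly 2, and one common-neighbor
#' (Jaccard) score per mapped GWAS gene (N columns in sorted gene-ID
#' order). The label marks genes that are known targets for the focal
#' disease.
#'
#' @param network An igraph interaction network.
#' @param gwas_genes The disease's GWAS reported genes; those not in the
#'   network are dropped (N counts only mapped genes; N = 0 is an error).
#' @param universe Candidate genes (typically all drug targets in the
#'   network); unmapped genes are dropped.
#' @param focal_targets Known targets for the focal disease (labels);
#'   must lie within the universe after mapping.
#' @return A `feature_matrix` tibble: `gene`, `label` (logical), then
#'   `gwas_first_neighbor_count`, `degree`, `gwas_second_neighbor_count`
#'   and N `cn_<GENE>` columns. Attribute `"n_gwas"` records N.
#' @export
build_feature_matrix <- function(network, gwas_genes, universe, focal_targets) {
  gwas <- sort(map_to_network(network, gwas_genes))
  uni <- sort(map_to_network(network, universe))
  targ <- sort(map_to_network(network, focal_targets))
  if (length(gwas) == 0) abort("no GWAS genes mapped to the network (N = 0)")
  if (length(uni) == 0) abort("no universe genes mapped to the network")
  if (!all(targ %in% uni)) abort("focal targets must be a subset of the universe")

  d <- igraph::distances(network, v = uni, to = gwas, algorithm = "unweighted")
  first_n <- as.integer(rowSums(d == 1))
  second_n <- as.integer(rowSums(d == 2))
  deg_all <- igraph::degree(network)

  # Jaccard via the sparse adjacency matrix: shared neighbors from a
  # cross-product, union from degree sums
  adj <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  shared <- as.matrix(adj[uni, , drop = FALSE] %*%
                        Matrix::t(adj[gwas, , drop = FALSE]))
  unions <- outer(deg_all[uni], deg_all[gwas], `+`) - shared
  jac <- ifelse(unions > 0, shared / unions, 0)
  colnames(jac) <- paste0("cn_", gwas)

  out <- tibble(
    gene = uni,
    label = uni %in% targ,
    gwas_first_neighbor_count = first_n,
    degree = as.integer(deg_all[uni]),
    gwas_second_neighbor_count = second_n
  ) %>%
    dplyr::bind_cols(as_tibble(jac))
  structure(out, n_gwas = length(gwas),
            class = c("feature_matrix", class(out)))
}

#' Feature columns of a feature matrix
#' @param matrix A `feature_matrix`.
#' @return Character vector of the 3 + N feature column names.
#' @export
feature_columns <- function(matrix) {
  setdiff(names(matrix), c("gene", "label"))
}

#' Diseases eligible for the network classifier
#'
#' A disease qualifies when at least `min_targets` of its drug targets
#' and at least `min_gwas` of its GWAS reported genes map into the
#' interaction network.
#'
#' @param maps A `disease_gene_map` tibble.
#' @param network An igraph interaction network.
#' @param min_targets,min_gwas Inclusive minimum mapped counts.
#' @return A tibble: `disease`, `n_gwas_mapped`, `n_targets_mapped`,
#'   `eligible`.
#' @export
eligible_diseases <- function(maps, network, min_targets = 10, min_gwas = 10) {
  nodes <- igraph::V(network)$name
  tibble(
    disease = maps$disease,
    n_gwas_mapped = map_int(maps$gwas_genes, ~ sum(.x %in% nodes)),
    n_targets_mapped = map_int(maps$target_genes, ~ sum(.x %in% nodes))
  ) %>%
    mutate(eligible = .data$n_targets_mapped >= min_targets &
             .data$n_gwas_mapped >= min_gwas)
}
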