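#' Build per-disease GWAS gene / drug target records
#'
#' Combines a long GWAS table (one row per disease-gene) and a long drug
#' table (one row per disease-drug-target) into one record per disease,
#' keeping only diseases present in both tables. Gene identifiers are
#' normalized (and optionally mapped through an alias table); rows whose
#' gene cannot be resolved are dropped and counted in the load report.
#' Duplicate rows for a disease are merged by set union.
#'
#' Disease labels are matched case-insensitively after whitespace collapse.
#' A merged label such as `"Bipolar disorder/Schizophrenia"` is treated as
#' one disease unit unless `split_merged = TRUE`, in which case it is split
#' on `"/"` into separate diseases sharing the same gene sets.
#'
#' @param gwas A data frame with columns `disease`, `gene` (GWAS reported
#'   genes per disease).
#' @param drugs A data frame with columns `disease`, `drug`, `target`;
#'   an optional `verified` column (logical, or `"yes"`/`"no"`) flags
#'   targets with documented pharmacological action.
#' @param alias Optional alias table (see [apply_gene_alias()]).
#' @param split_merged Split `"/"`-merged disease labels into separate
#'   diseases.
#' @return A `disease_gene_map` tibble with one row per disease and
#'   list-columns `gwas_genes`, `drugs`, `target_genes`, `verified_targets`
#'   plus the set sizes `m` (GWAS genes) and `n` (targets). The attribute
#'   `"load_report"` records dropped-gene counts.
#' @seealso [load_disease_gene_map()] to read the two tables from TSV.
#' @export
disease_gene_map <- function(gwas, drugs, alias = NULL, split_merged = FALSE) {
  stopifnot(is.data.frame(gwas), is.data.frame(drugs))
  need <- setdiff(c("disease", "gene"), names(gwas))
  if (length(need)) abort(paste("gwas table: missing column(s):", paste(need, collapse = ", ")))
  need <- setdiff(c("disease", "drug", "target"), names(drugs))
  if (length(need)) abort(paste("drug table: missing column(s):", paste(need, collapse = ", ")))

  if (split_merged) {
    gwas <- tidyr::separate_longer_delim(gwas, "disease", delim = "/")
    drugs <- tidyr::separate_longer_delim(drugs, "disease", delim = "/")
  }
  gwas <- gwas %>%
    mutate(
      disease_key = normalize_disease(.data$disease),
      gene = apply_gene_alias(.data$gene, alias)
    )
  if (!"verified" %in% names(drugs)) {
    drugs$verified <- rep(FALSE, nrow(drugs))
  }
  drugs <- drugs %>%
    mutate(
      disease_key = normalize_disease(.data$disease),
      target = apply_gene_alias(.data$target, alias),
      verified = parse_yes_no(.data$verified)
    )

  dropped_gwas <- sum(is.na(gwas$gene))
  dropped_targets <- sum(is.na(drugs$target))
  gwas <- filter(gwas, !is.na(.data$gene))
  drugs_ok <- filter(drugs, !is.na(.data$target))

  shared <- intersect(unique(gwas$disease_key), unique(drugs$disease_key))

  gw <- gwas %>%
    filter(.data$disease_key %in% shared) %>%
    group_by(.data$disease_key) %>%
    summarise(
      disease = dplyr::first(.data$disease),
      gwas_genes = list(sort(unique(.data$gene)))
    )
  dr <- drugs_ok %>%
    filter(.data$disease_key %in% shared) %>%
    group_by(.data$disease_key) %>%
    summarise(
      drugs = list(sort(unique(.data$drug))),
      target_genes = list(sort(unique(.data$target))),
      verified_targets = list(sort(unique(.data$target[.data$verified])))
    )

  maps <- inner_join(gw, dr, by = "disease_key") %>%
    mutate(
      m = map_int(.data$gwas_genes, length),
      n = map_int(.data$target_genes, length)
    ) %>%
    select("disease", "gwas_genes", "drugs", "target_genes",
           "verified_targets", "m", "n") %>%
    arrange(.data$disease)

  structure(
    maps,
    load_report = list(
      dropped_gwas_genes = dropped_gwas,
      dropped_target_genes = dropped_targets,
      diseases_gwas_only = length(setdiff(unique(gwas$disease_key), shared)),
      diseases_drug_only = length(setdiff(unique(drugs_ok$disease_key), shared))
    ),
    class = c("disease_gene_map", class(maps))
  )
}

parse_yes_no <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(trimws(as.character(x))) %in% c("yes", "true", "1", "y")
}

#' Load disease gene maps from TSV files
#'
#' @param gwas_path TSV with header columns `disease`, `gene`.
#' @param drug_path TSV with header columns `disease`, `drug`, `target`
#'   and optionally `verified`.
#' @param alias_path Optional two-column alias TSV (`alias`, `gene`).
#' @inheritParams disease_gene_map
#' @return A `disease_gene_map` tibble; see [disease_gene_map()].
#' @export
load_disease_gene_map <- function(gwas_path, drug_path, alias_path = NULL,
                                  split_merged = FALSE) {
  gwas <- read_tsv_checked(gwas_path, required = c("disease", "gene"))
  drugs <- read_tsv_checked(drug_path, required = c("disease", "drug", "target"))
  alias <- if (!is.null(alias_path)) load_alias_table(alias_path) else NULL
  disease_gene_map(gwas, drugs, alias = alias, split_merged = split_merged)
}

#' Write a disease gene map back to its two long TSV tables
#'
#' Inverse of [load_disease_gene_map()]: the written tables round-trip to
#' identical gene sets.
#'
#' @param maps A `disease_gene_map` tibble.
#' @param gwas_path,drug_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_disease_gene_map <- function(maps, gwas_path, drug_path) {
  gw <- maps %>%
    select("disease", "gwas_genes") %>%
    tidyr::unnest("gwas_genes") %>%
    rename(gene = "gwas_genes")
  dr <- maps %>%
    select("disease", "drugs", "target_genes", "verified_targets") %>%
    pmap(function(disease, drugs, target_genes, verified_targets) {
      tidyr::expand_grid(disease = disease, drug = drugs, target = target_genes) %>%
        mutate(verified = .data$target %in% verified_targets)
    }) %>%
    bind_rows()
  readr::write_tsv(gw, gwas_path)
  readr::write_tsv(dr, drug_path)
  invisible(c(gwas_path, drug_path))
}

#' Load a locus-to-gene map for linkage-disequilibrium expansion
#'
#' Each locus lists all genes in linkage disequilibrium with its marker
#' SNP. Every locus must contain at least one gene (guaranteed by the long
#' format; blank gene rows are an error).
#'
#' @param path TSV with header columns `locus`, `gene`.
#' @param alias Optional alias table.
#' @return A tibble with columns `locus` and `gene` (normalized).
#' @export
load_locus_map <- function(path, alias = NULL) {
  tab <- read_tsv_checked(path, required = c("locus", "gene"))
  tab$gene <- apply_gene_alias(tab$gene, alias)
  if (anyNA(tab$gene)) {
    abort("locus map: locus with an empty/unresolvable gene entry")
  }
  dplyr::distinct(as_tibble(tab[, c("locus", "gene")]))
}

#' Load a per-gene annotation table
#'
#' Protein length (residues), longest transcript length (bases) and dN/dS
#' ratios for human-mouse and human-chimpanzee ortholog pairs. Missing
#' dN/dS values are recorded as `NA`, never as 0; non-positive lengths are
#' rejected.
#'
#' @param path TSV with header columns `gene`, `protein_length`,
#'   `longest_transcript_length`, and optionally `dnds_mouse`,
#'   `dnds_chimp`.
#' @param alias Optional alias table.
#' @return A tibble, one row per gene.
#' @export
load_gene_annotation <- function(path, alias = NULL) {
  tab <- read_tsv_checked(
    path,
    required = c("gene", "protein_length", "longest_transcript_length")
  )
  tab$gene <- apply_gene_alias(tab$gene, alias)
  tab <- filter(tab, !is.na(.data$gene))
  for (col in c("dnds_mouse", "dnds_chimp")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_real_
  }
  bad <- tab$protein_length <= 0 | tab$longest_transcript_length <= 0
  if (any(bad, na.rm = TRUE)) {
    abort("gene annotation: non-positive protein or transcript length")
  }
  dplyr::distinct(as_tibble(tab[, c(
    "gene", "protein_length", "longest_transcript_length",
    "dnds_mouse", "dnds_chimp"
  )]), .data$gene, .keep_all = TRUE)
}
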