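#' Expected overlap of two gene lists under a random model
#'
#' Assume a genome of `genome_size` genes (20,000 by default). If a
#' disease has `m` GWAS reported genes and `n` drug target genes drawn
#' independently, the expected number of genes in both lists is
#' `m * n / genome_size`. Summing this quantity over diseases gives the
#' expected total overlap under the null of no relationship.
#'
#' @param m,n Non-negative gene counts (vectorized).
#' @param genome_size Assumed number of human genes; must be > 0.
#' @return `m * n / genome_size`, a numeric vector.
#' @examples
#' expected_random_overlap(100, 114) # 0.57
#' @export
expected_random_overlap <- function(m, n, genome_size = 20000) {
  if (any(genome_size <= 0)) abort("genome_size must be > 0")
  if (any(m < 0) || any(n < 0)) abort("m and n must be non-negative")
  m * n / genome_size
}

#' Per-disease overlap between GWAS genes and drug targets
#'
#' For each disease, counts the genes that are both GWAS reported genes
#' and drug targets for that same disease, alongside the expected overlap
#' under the random model. Summary statistics (totals, the mean observed
#' overlap per disease, and the number of unique overlapping genes across
#' diseases) are available via [glance()].
#'
#' @param maps A `disease_gene_map` tibble (see [disease_gene_map()]).
#' @param verified_only Use only targets with documented pharmacological
#'   action as the target set.
#' @param genome_size Genome size for the random model.
#' @param n_diseases Denominator for the mean observed overlap. Defaults
#'   to the number of map records; supply a larger count when merged trait
#'   rows represent several diseases.
#' @return An `overlap_summary` tibble with one row per disease:
#'   `disease`, `m`, `n`, `observed_overlap`, `expected_overlap` and the
#'   list-column `overlapping_genes`.
#' @export
compute_overlap <- function(maps, verified_only = FALSE, genome_size = 20000,
                            n_diseases = NULL) {
  stopifnot(is.data.frame(maps))
  targets <- if (verified_only) maps$verified_targets else maps$target_genes
  per <- tibble(
    disease = maps$disease,
    m = map_int(maps$gwas_genes, length),
    n = map_int(targets, length),
    overlapping_genes = map2(maps$gwas_genes, targets, intersect)
  ) %>%
    mutate(
      observed_overlap = map_int(.data$overlapping_genes, length),
      expected_overlap = expected_random_overlap(.data$m, .data$n, genome_size)
    ) %>%
    select("disease", "m", "n", "observed_overlap", "expected_overlap",
           "overlapping_genes")

  structure(
    per,
    n_diseases = n_diseases %||% nrow(per),
    genome_size = genome_size,
    verified_only = verified_only,
    class = c("overlap_summary", class(per))
  )
}

#' @rdname compute_overlap
#' @param x An `overlap_summary`.
#' @param ... Unused.
#' @method glance overlap_summary
#' @export
glance.overlap_summary <- function(x, ...) {
  nd <- attr(x, "n_diseases")
  tibble(
    n_records = nrow(x),
    n_diseases = nd,
    total_observed = sum(x$observed_overlap),
    total_expected = sum(x$expected_overlap),
    mean_observed = sum(x$observed_overlap) / nd,
    unique_overlapping_genes = length(unique(unlist(x$overlapping_genes)))
  )
}

#' @rdname compute_overlap
#' @method tidy overlap_summary
#' @export
tidy.overlap_summary <- function(x, ...) {
  as_tibble(x) %>%
    mutate(overlapping_genes = map_chr(
      .data$overlapping_genes, paste, collapse = ","
    ))
}

#' @export
print.overlap_summary <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Overlap summary: %d disease records (%d diseases)\n", g$n_records, g$n_diseases
  ))
  cat(sprintf(
    "  observed total %d (mean %.2f/disease), expected %.2f, unique genes %d\n",
    g$total_observed, g$mean_observed, g$total_expected,
    g$unique_overlapping_genes
  ))
  NextMethod()
}

#' Expand GWAS candidate sets by linkage-disequilibrium locus
#'
#' Replaces each disease's reported GWAS gene set by the union of the
#' reported genes and all genes belonging to any locus that contains a
#' reported gene — i.e. all genes in linkage disequilibrium with the same
#' marker are treated as candidates. Gene counts never decrease.
#'
#' @param maps A `disease_gene_map` tibble.
#' @param loci A locus map tibble (`locus`, `gene`); see
#'   [load_locus_map()].
#' @return The maps with expanded `gwas_genes` and updated `m`.
#' @export
expand_candidates_by_locus <- function(maps, loci) {
  stopifnot(is.data.frame(loci), all(c("locus", "gene") %in% names(loci)))
  if (nrow(loci) == 0) return(maps)
  locus_genes <- split(normalize_gene_id(loci$gene), loci$locus)
  gene_locus <- split(loci$locus, normalize_gene_id(loci$gene))
  maps$gwas_genes <- map(maps$gwas_genes, function(genes) {
    hit_loci <- unique(unlist(gene_locus[genes]))
    sort(union(genes, unlist(locus_genes[hit_loci])))
  })
  maps$m <- map_int(maps$gwas_genes, length)
  maps
}

#' The packaged GWAS/drug-target overlap count table
#'
#' Per-disease counts of drugs, GWAS reported genes, drug targets, and the
#' observed overlaps (same-disease and any-disease), for the GWAS diseases
#' that have drugs; transcribed from the study's summary table.
#'
#' @return A tibble with columns `disease`, `n_drugs`, `n_gwas_genes`,
#'   `n_targets`, `overlap_same_disease`, `overlap_all_diseases`.
#' @export
gwas_drug_overlap_table <- function() {
  path <- system.file("extdata", "gwas_drug_overlap.tsv", package = "targetnet")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Construct explicit gene sets matching an overlap count table
#'
#' Builds a deterministic `disease_gene_map` whose per-disease GWAS and
#' target gene-set sizes and same-disease overlaps equal the counts in an
#' overlap table such as [gwas_drug_overlap_table()]. Overlapping genes
#' are drawn from a shared pool in which `n_shared` gene IDs each recur in
#' two different diseases, so the number of unique overlapping genes is
#' `total overlap - n_shared` (the study's 23 instances over 20 genes).
#'
#' @param counts An overlap count table with columns `disease`,
#'   `n_gwas_genes`, `n_targets`, `overlap_same_disease`.
#' @param n_shared Number of overlap gene IDs reused across two diseases.
#' @return A `disease_gene_map` tibble.
#' @export
build_overlap_fixture <- function(counts = gwas_drug_overlap_table(),
                                  n_shared = 3) {
  total <- sum(counts$overlap_same_disease)
  if (n_shared >= total) abort("n_shared must be smaller than the total overlap")
  pool_ids <- sprintf("OV%03d", seq_len(total - n_shared))
  # first occurrences take fresh IDs; the last n_shared instances reuse the
  # first IDs, landing in different diseases than the originals
  instance_ids <- c(pool_ids, pool_ids[seq_len(n_shared)])[seq_len(total)]

  rows <- vector("list", nrow(counts))
  slot <- 0L
  for (i in seq_len(nrow(counts))) {
    k <- counts$overlap_same_disease[i]
    ov <- character(0)
    if (k > 0) {
      ov <- instance_ids[slot + seq_len(k)]
      slot <- slot + k
    }
    m <- counts$n_gwas_genes[i]
    n <- counts$n_targets[i]
    gwas <- c(ov, sprintf("D%02dG%03d", i, seq_len(m - k)))
    targ <- c(ov, sprintf("D%02dT%03d", i, seq_len(n - k)))
    n_drugs <- if ("n_drugs" %in% names(counts)) counts$n_drugs[i] else 1L
    rows[[i]] <- tibble(
      disease = counts$disease[i],
      gwas_genes = list(sort(normalize_gene_id(gwas))),
      drugs = list(sprintf("drug_%02d_%02d", i, seq_len(n_drugs))),
      target_genes = list(sort(normalize_gene_id(targ))),
      verified_targets = list(character(0)),
      m = m, n = n
    )
  }
  out <- bind_rows(rows)
  structure(out, class = c("disease_gene_map", class(out)))
}
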