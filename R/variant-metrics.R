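#' Per-gene non-synonymous SNP density for a gene class
#'
#' The density for a gene is its number of non-synonymous SNPs divided by
#' its protein length in residues; the "common" density counts only SNPs
#' with allele frequency strictly greater than `common_threshold`
#' (frequency > 5% by default). Genes in the class with no recorded
#' variants have density 0; genes without a protein length are excluded
#' and counted. Variant records are deduplicated by genomic position
#' within a gene, so density is invariant to record order and repeats.
#'
#' @param variants A variant table (see [load_variants()]).
#' @param annotation A gene annotation table with `gene` and
#'   `protein_length` (see [load_gene_annotation()]).
#' @param genes Character vector: the gene class to profile.
#' @param common_threshold Allele-frequency cutoff; a SNP is "common" when
#'   its frequency is strictly greater than this value.
#' @param pooled Also compute pooled densities (total SNP count over total
#'   residues) in [glance()]; the default summary is the unweighted
#'   per-gene mean.
#' @return A `density_result` tibble, one row per retained gene:
#'   `gene`, `protein_length`, `n_all`, `n_common`, `density_all`,
#'   `density_common`. Class means via [glance()].
#' @export
snp_density <- function(variants, annotation, genes,
                        common_threshold = 0.05, pooled = FALSE) {
  genes <- unique(normalize_gene_id(genes))
  genes <- genes[!is.na(genes)]
  ann <- annotation %>%
    filter(.data$gene %in% genes, !is.na(.data$protein_length))
  n_excluded <- length(genes) - nrow(ann)

  v <- variants %>%
    filter(.data$gene %in% ann$gene) %>%
    distinct(.data$gene, .data$chrom, .data$pos, .keep_all = TRUE)
  counts <- v %>%
    group_by(.data$gene) %>%
    summarise(
      n_all = n(),
      n_common = sum(.data$allele_frequency > common_threshold)
    )

  per_gene <- ann %>%
    select("gene", "protein_length") %>%
    left_join(counts, by = "gene") %>%
    mutate(
      n_all = dplyr::coalesce(.data$n_all, 0L),
      n_common = dplyr::coalesce(.data$n_common, 0L),
      density_all = .data$n_all / .data$protein_length,
      density_common = .data$n_common / .data$protein_length
    ) %>%
    arrange(.data$gene)

  structure(
    per_gene,
    n_excluded_no_length = n_excluded,
    common_threshold = common_threshold,
    pooled = pooled,
    class = c("density_result", class(per_gene))
  )
}

#' @rdname snp_density
#' @param x A `density_result`.
#' @param ... Unused.
#' @method glance density_result
#' @export
glance.density_result <- function(x, ...) {
  out <- tibble(
    n_genes = nrow(x),
    n_excluded_no_length = attr(x, "n_excluded_no_length"),
    common_threshold = attr(x, "common_threshold"),
    density_all_nonsyn = mean(x$density_all),
    density_common_nonsyn = mean(x$density_common)
  )
  if (isTRUE(attr(x, "pooled"))) {
    out$pooled_density_all <- sum(x$n_all) / sum(x$protein_length)
    out$pooled_density_common <- sum(x$n_common) / sum(x$protein_length)
  }
  out
}

#' Contrast longest transcript lengths between two gene classes
#'
#' GWAS reported genes tend to be about twice as long as drug target
#' genes; this computes per-class longest-transcript length vectors, the
#' rank-sum comparison, and the median length ratio. [autoplot()] shows
#' the log10 length distributions.
#'
#' @param annotation A gene annotation table with
#'   `longest_transcript_length`.
#' @param class_a,class_b Character vectors of gene IDs (e.g. GWAS genes
#'   and drug targets).
#' @param labels Length-2 labels for the two classes.
#' @param paired Use a signed-rank test on positionally matched pairs
#'   (requires equal class sizes); default is the unpaired rank-sum test.
#' @return A `length_contrast` list: `lengths` (tibble of `class`,
#'   `gene`, `length`), `test` (see [compare_gene_classes()]),
#'   `median_ratio` (median a / median b).
#' @export
longest_transcript_contrast <- function(annotation, class_a, class_b,
                                        labels = c("class_a", "class_b"),
                                        paired = FALSE) {
  len_of <- function(genes) {
    annotation %>%
      filter(.data$gene %in% normalize_gene_id(genes),
             !is.na(.data$longest_transcript_length)) %>%
      select("gene", length = "longest_transcript_length")
  }
  a <- len_of(class_a)
  b <- len_of(class_b)
  test <- compare_gene_classes(a$length, b$length, paired = paired)
  structure(
    list(
      lengths = bind_rows(
        mutate(a, class = labels[1]),
        mutate(b, class = labels[2])
      ) %>% select("class", "gene", "length"),
      test = test,
      median_ratio = median(a$length) / median(b$length)
    ),
    class = "length_contrast"
  )
}

#' @rdname longest_transcript_contrast
#' @param x A `length_contrast`.
#' @param ... Unused.
#' @method glance length_contrast
#' @export
glance.length_contrast <- function(x, ...) {
  x$lengths %>%
    group_by(.data$class) %>%
    summarise(n = n(), mean_length = mean(.data$length),
              median_length = median(.data$length)) %>%
    mutate(median_ratio = x$median_ratio, p_value = x$test$p_value)
}

#' @rdname longest_transcript_contrast
#' @param object A `length_contrast`.
#' @method autoplot length_contrast
#' @export
autoplot.length_contrast <- function(object, ...) {
  ggplot2::ggplot(object$lengths,
                  ggplot2::aes(x = log10(.data$length),
                               colour = .data$class)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "log10 longest transcript length (bases)",
                  y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Contrast dN/dS between gene classes and the all-genes background
#'
#' For the chosen ortholog pair (human-chimp or human-mouse), reports each
#' class's mean dN/dS and its Mann-Whitney p-value against the all-genes
#' background; classes other than `gwas` are additionally tested against
#' the GWAS class when one is supplied. A dN/dS below the background mean
#' indicates stronger purifying selection. Genes missing the requested
#' ratio are excluded per class; classes left with fewer than 2 annotated
#' genes are dropped with a warning.
#'
#' @param annotation A gene annotation table with `dnds_mouse` /
#'   `dnds_chimp`.
#' @param classes Named list of gene-ID vectors (e.g.
#'   `list(gwas = ..., drug_target = ...)`). The background class `all`
#'   (every annotated gene) is always included.
#' @param ortholog `"chimp"` or `"mouse"`.
#' @return A tibble: `class`, `n`, `mean_dnds`, `p_vs_all`, `p_vs_gwas`.
#' @export
dnds_contrast <- function(annotation, classes, ortholog = c("chimp", "mouse")) {
  ortholog <- match.arg(ortholog)
  col <- paste0("dnds_", ortholog)
  stopifnot(is.list(classes), !is.null(names(classes)))
  ann <- annotation %>% filter(!is.na(.data[[col]]))
  values_of <- function(genes) {
    ann[[col]][ann$gene %in% normalize_gene_id(genes)]
  }
  vals <- map(classes, values_of)
  small <- map_lgl(vals, ~ length(.x) < 2)
  if (any(small)) {
    warn(paste(
      "dropping class(es) with < 2 annotated genes:",
      paste(names(vals)[small], collapse = ", ")
    ))
    vals <- vals[!small]
  }
  all_vals <- ann[[col]]
  gwas_vals <- vals[["gwas"]]
  rows <- imap(vals, function(v, nm) {
    tibble(
      class = nm,
      n = length(v),
      mean_dnds = mean(v),
      p_vs_all = compare_gene_classes(v, all_vals)$p_value,
      p_vs_gwas = if (!is.null(gwas_vals) && nm != "gwas") {
        compare_gene_classes(v, gwas_vals)$p_value
      } else {
        NA_real_
      }
    )
  })
  bind_rows(
    tibble(class = "all", n = length(all_vals), mean_dnds = mean(all_vals),
           p_vs_all = NA_real_, p_vs_gwas = NA_real_),
    bind_rows(rows)
  )
}
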