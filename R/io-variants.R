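#' Load non-synonymous variants and genotype-derived allele frequencies
#'
#' Reads a VCF 4.x file with per-sample genotypes, keeps sites whose
#' annotation INFO field matches the non-synonymous tag, and computes the
#' alternate allele frequency from the genotype columns: a heterozygote
#' contributes 1 alternate allele, a homozygote 2, and the denominator is
#' the number of called alleles (2 x the number of genotyped individuals
#' when no calls are missing). Ploidy is assumed diploid; half-missing
#' genotypes such as `./1` contribute only their called allele to both
#' numerator and denominator. Sites with no called genotypes are skipped
#' and counted in the `"n_skipped_no_genotypes"` attribute.
#'
#' @param path Path to a VCF file.
#' @param gene_field Name of the INFO key carrying the gene identifier
#'   (default `"GENE"`).
#' @param effect_field Name of the INFO key carrying the consequence
#'   annotation (default `"EFF"`); set to `NULL` to keep all sites.
#' @param nonsyn_tag Value of `effect_field` that marks a non-synonymous
#'   site (substring match, default `"nonsynonymous"`).
#' @param alias Optional alias table for the gene identifiers.
#' @return A tibble with one row per retained site: `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `alt_allele_count`, `total_allele_count`,
#'   `allele_frequency`.
#' @export
load_variants <- function(path, gene_field = "GENE", effect_field = "EFF",
                          nonsyn_tag = "nonsynonymous", alias = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(empty_variant_table())
  }
  info <- fix$INFO %||% rep("", nrow(fix))
  gene <- vcf_info_field(info, gene_field)
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(effect_field)) {
    eff <- vcf_info_field(info, effect_field)
    keep <- !is.na(eff) & grepl(nonsyn_tag, eff, fixed = TRUE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  counts <- t(apply(gt, 1, count_gt_alleles))

  tab <- tibble(
    gene = apply_gene_alias(gene, alias),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    alt_allele_count = as.integer(counts[, 1]),
    total_allele_count = as.integer(counts[, 2])
  )[keep, , drop = FALSE]

  no_gt <- tab$total_allele_count == 0
  out <- tab %>%
    filter(!no_gt, !is.na(.data$gene)) %>%
    mutate(allele_frequency = .data$alt_allele_count / .data$total_allele_count)
  attr(out, "n_skipped_no_genotypes") <- sum(no_gt)
  out
}

empty_variant_table <- function() {
  tibble(
    gene = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(),
    alt_allele_count = integer(), total_allele_count = integer(),
    allele_frequency = double()
  )
}

# alt/called allele counts for one site's GT strings (diploid "0/1", "1|1", "./1", ...)
count_gt_alleles <- function(gts) {
  alleles <- unlist(strsplit(gts[!is.na(gts)], "[/|]"))
  called <- alleles[alleles != "." & nzchar(alleles)]
  c(alt = sum(called != "0"), total = length(called))
}

vcf_info_field <- function(info, key) {
  pattern <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pattern, info))
  map_chr(m, function(x) if (length(x) >= 2) x[2] else NA_character_)
}
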