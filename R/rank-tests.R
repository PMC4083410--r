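#' Compare two gene classes with a rank-based test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test between per-gene
#' values of two classes; with `paired = TRUE`, the Wilcoxon signed-rank
#' test on matched pairs. Small samples without ties use the exact null
#' distribution, larger ones the normal approximation with continuity
#' correction (the `stats::wilcox.test` defaults).
#'
#' @param values_a,values_b Numeric vectors of per-gene values; both must
#'   be non-empty (and of equal length when `paired = TRUE`).
#' @param paired Use the signed-rank test on matched pairs.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) p-values;
#'   `NULL` keeps the `wilcox.test` default.
#' @return A one-row tibble: `statistic` (the rank-sum statistic W),
#'   `p_value`, `n_a`, `n_b`, `method`, and the medians of both samples.
#' @export
compare_gene_classes <- function(values_a, values_b, paired = FALSE,
                                 exact = NULL) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("both samples must be non-empty")
  }
  if (min(length(values_a), length(values_b)) < 5 && !paired) {
    warn("rank-sum test on fewer than 5 observations per class; p-value is coarse")
  }
  ht <- suppressWarnings(
    wilcox.test(values_a, values_b, paired = paired, exact = exact)
  )
  p <- ht$p.value
  # fully tied samples have no evidence of a shift; the normal
  # approximation returns 0/0 there
  if (is.nan(p)) p <- 1
  tibble(
    statistic = unname(ht$statistic),
    p_value = p,
    n_a = length(values_a),
    n_b = length(values_b),
    median_a = median(values_a),
    median_b = median(values_b),
    method = if (paired) "wilcoxon signed-rank" else "mann-whitney rank-sum"
  )
}
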