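#' Normalize gene identifiers to a canonical string token
#'
#' Gene identifiers from different sources (symbols, accession-style IDs)
#' are compared by exact string equality after normalization: surrounding
#' whitespace is stripped, internal whitespace collapsed, and case folded
#' to upper. Normalization is idempotent.
#'
#' @param x Character vector of raw gene identifiers.
#' @return Character vector of normalized identifiers; empty tokens become
#'   `NA` so callers can drop and count them.
#' @examples
#' normalize_gene_id(c(" tp53", "EGFR ", "abc  1"))
#' @export
normalize_gene_id <- function(x) {
  x <- stringr::str_squish(toupper(as.character(x)))
  x[!nzchar(x)] <- NA_character_
  x
}

#' Apply an alias table mapping raw identifiers to canonical gene IDs
#'
#' The alias table is a two-column mapping (`alias`, `gene`). Identifiers
#' without an alias entry are kept as-is when `keep_unmapped = TRUE`
#' (the mapping is treated as a rename layer) or dropped to `NA` otherwise.
#' Both sides are normalized before matching.
#'
#' @param x Character vector of gene identifiers.
#' @param alias A data frame with columns `alias` and `gene`, or `NULL`
#'   for the identity mapping.
#' @param keep_unmapped Keep identifiers absent from the table unchanged
#'   (default) instead of mapping them to `NA`.
#' @return Character vector of canonical identifiers.
#' @export
apply_gene_alias <- function(x, alias = NULL, keep_unmapped = TRUE) {
  x <- normalize_gene_id(x)
  if (is.null(alias)) {
    return(x)
  }
  stopifnot(is.data.frame(alias), all(c("alias", "gene") %in% names(alias)))
  key <- normalize_gene_id(alias$alias)
  val <- normalize_gene_id(alias$gene)
  idx <- match(x, key)
  out <- val[idx]
  if (keep_unmapped) {
    out[is.na(idx)] <- x[is.na(idx)]
  }
  out
}

# disease labels: case-insensitive match after whitespace collapse
normalize_disease <- function(x) {
  stringr::str_squish(tolower(as.character(x)))
}

#' Read a two-column gene alias table
#'
#' @param path Path to a TSV with header columns `alias` and `gene`.
#' @return A tibble with columns `alias` and `gene`.
#' @export
load_alias_table <- function(path) {
  tab <- read_tsv_checked(path, required = c("alias", "gene"))
  dplyr::distinct(tab[, c("alias", "gene")])
}

# shared TSV reader: header row required, named-column validation
read_tsv_checked <- function(path, required = character()) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s: missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  tab
}
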