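make_variants <- function(gene, n, af) {
  tibble::tibble(
    gene = gene, chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
    alt_allele_count = round(af * 100), total_allele_count = 100L,
    allele_frequency = af
  )
}

test_that("per-gene density is count over protein length", {
  ann <- tibble::tibble(gene = c("G1", "G2"), protein_length = c(600, 100),
                        longest_transcript_length = 1, dnds_mouse = NA,
                        dnds_chimp = NA)
  v <- make_variants("G1", 5, af = c(0.2, 0.3, 0.5, 0.01, 0.04))
  d <- snp_density(v, ann, c("G1", "G2"))
  expect_equal(d$density_common[d$gene == "G1"], 3 / 600)
  expect_equal(d$density_all[d$gene == "G1"], 5 / 600)
  # gene without variants has zero densities
  expect_equal(d$density_all[d$gene == "G2"], 0)
  expect_true(all(d$density_common <= d$density_all))
})

test_that("common means allele frequency strictly above the threshold", {
  ann <- tibble::tibble(gene = "G1", protein_length = 100,
                        longest_transcript_length = 1, dnds_mouse = NA,
                        dnds_chimp = NA)
  v <- make_variants("G1", 3, af = c(0.05, 0.0500001, 0.051))
  d <- snp_density(v, ann, "G1")
  expect_equal(d$n_common, 2L) # exactly 5% is not common
})

test_that("density is invariant to record order and duplicated records", {
  ann <- tibble::tibble(gene = "G1", protein_length = 250,
                        longest_transcript_length = 1, dnds_mouse = NA,
                        dnds_chimp = NA)
  v <- make_variants("G1", 6, af = runif(6, 0.1, 0.4))
  shuffled <- v[sample(nrow(v)), ]
  duplicated <- rbind(v, v[3:4, ])
  base <- snp_density(v, ann, "G1")
  expect_equal(snp_density(shuffled, ann, "G1")$density_common,
               base$density_common)
  expect_equal(snp_density(duplicated, ann, "G1")$density_common,
               base$density_common)
})

test_that("raising the common threshold never increases common density", {
  ann <- tibble::tibble(gene = "G1", protein_length = 300,
                        longest_transcript_length = 1, dnds_mouse = NA,
                        dnds_chimp = NA)
  set.seed(8)
  v <- make_variants("G1", 30, af = runif(30, 0, 0.5))
  prev <- Inf
  for (thr in c(0.01, 0.05, 0.1, 0.2, 0.4)) {
    cur <- snp_density(v, ann, "G1", common_threshold = thr)$density_common
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("genes without protein length are excluded and counted", {
  ann <- tibble::tibble(gene = "G1", protein_length = 100,
                        longest_transcript_length = 1, dnds_mouse = NA,
                        dnds_chimp = NA)
  d <- snp_density(make_variants("G1", 1, 0.2), ann, c("G1", "G2"))
  expect_equal(nrow(d), 1)
  expect_equal(glance(d)$n_excluded_no_length, 1)
})

test_that("recovered class density sits near the planted per-residue rate", {
  ng <- 500
  set.seed(12)
  len <- pmax(30, round(rlnorm(ng, log(450), 0.5)))
  genes <- sprintf("G%04d", seq_len(ng))
  gv <- gen_variants(genes, len, rate_per_residue = 0.00221,
                     common_fraction = 1, n_individuals = 30, seed = 13)
  ann <- tibble::tibble(gene = genes, protein_length = len,
                        longest_transcript_length = 1,
                        dnds_mouse = NA, dnds_chimp = NA)
  d <- glance(snp_density(gv$variants, ann, genes))
  # per-gene density is Poisson(rate*L)/L; bound the class mean by 3 SE
  se <- sqrt(sum(0.00221 / len) / ng^2)
  expect_lt(abs(d$density_all_nonsyn - 0.00221), 3 * se)
})

test_that("transcript contrast recovers a planted two-fold length ratio", {
  n <- 1000
  genes <- sprintf("G%04d", 1:(2 * n))
  ga <- gen_annotation(
    genes, classes = list(gwas = genes[1:n], drug_target = genes[(n + 1):(2 * n)]),
    seed = 21
  )
  lc <- longest_transcript_contrast(ga$annotation, genes[1:n],
                                    genes[(n + 1):(2 * n)],
                                    labels = c("gwas", "drug_target"))
  expect_lt(lc$test$p_value, 0.05)
  expect_lt(abs(lc$median_ratio - 110 / 60), 0.1 * 110 / 60)
  p <- autoplot(lc)
  expect_s3_class(p, "ggplot")
})

test_that("identical classes show no length difference", {
  genes <- sprintf("G%03d", 1:200)
  ga <- gen_annotation(genes, seed = 3)
  lc <- longest_transcript_contrast(ga$annotation, genes, genes)
  expect_gt(lc$test$p_value, 0.9)
  expect_equal(lc$median_ratio, 1)
})

test_that("single-gene classes still yield a statistic, with a warning", {
  ann <- tibble::tibble(gene = c("A", "B"), protein_length = 10,
                        longest_transcript_length = c(1000, 2000),
                        dnds_mouse = NA, dnds_chimp = NA)
  expect_warning(
    lc <- longest_transcript_contrast(ann, "A", "B"),
    "fewer than 5"
  )
  expect_true(is.finite(lc$test$statistic))
})

test_that("constant dN/dS gives equal class means and p near 1", {
  genes <- sprintf("G%03d", 1:60)
  ann <- tibble::tibble(gene = genes, protein_length = 10,
                        longest_transcript_length = 10,
                        dnds_mouse = 0.5, dnds_chimp = 0.5)
  res <- dnds_contrast(ann, list(gwas = genes[1:20],
                                 drug_target = genes[21:40]),
                       ortholog = "chimp")
  expect_true(all(res$mean_dnds == 0.5))
  expect_true(all(res$p_vs_all[-1] > 0.9))
})

test_that("planted purifying selection in targets is recovered", {
  hits <- 0
  for (s in 1:20) {
    genes <- sprintf("G%04d", 1:1500)
    ga <- gen_annotation(
      genes,
      classes = list(gwas = genes[1:300], drug_target = genes[301:600]),
      seed = s
    )
    res <- dnds_contrast(ga$annotation,
                         list(gwas = genes[1:300],
                              drug_target = genes[301:600]),
                         ortholog = "chimp")
    tgt <- res[res$class == "drug_target", ]
    all_mean <- res$mean_dnds[res$class == "all"]
    if (tgt$mean_dnds < all_mean && tgt$p_vs_all < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("classes losing all annotated genes are dropped with a warning", {
  ann <- tibble::tibble(gene = c("A", "B", "C", "D"), protein_length = 10,
                        longest_transcript_length = 10,
                        dnds_mouse = NA,
                        dnds_chimp = c(0.1, 0.2, 0.3, NA))
  w <- capture_warnings(
    res <- dnds_contrast(ann, list(gwas = c("A", "B"), drug_target = "D"),
                         ortholog = "chimp")
  )
  expect_true(any(grepl("drug_target", w)))
  expect_false("drug_target" %in% res$class)
})
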