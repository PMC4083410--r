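test_that("gene identifier normalization is idempotent and total", {
  raw <- c(" tp53", "EGFR ", "abc  1", "", "  ", "Brca1")
  once <- normalize_gene_id(raw)
  expect_identical(normalize_gene_id(once), once)
  expect_identical(once[1:3], c("TP53", "EGFR", "ABC 1"))
  expect_true(all(is.na(once[4:5])))
})

test_that("alias mapping renames known IDs and keeps or drops the rest", {
  alias <- data.frame(alias = c("p53", "her2"), gene = c("TP53", "ERBB2"))
  expect_identical(apply_gene_alias(c("P53", "EGFR"), alias),
                   c("TP53", "EGFR"))
  expect_identical(apply_gene_alias(c("P53", "EGFR"), alias,
                                    keep_unmapped = FALSE),
                   c("TP53", NA))
})

test_that("disease map merges duplicate disease rows by set union", {
  gwas <- data.frame(disease = c("Asthma", "asthma ", "Asthma"),
                     gene = c("A", "B", "A"))
  drugs <- data.frame(disease = "ASTHMA", drug = "d1", target = "T1")
  maps <- disease_gene_map(gwas, drugs)
  expect_equal(nrow(maps), 1)
  expect_setequal(maps$gwas_genes[[1]], c("A", "B"))
  expect_equal(maps$m, 2L)
})

test_that("diseases must appear in both tables; empty drug table yields none", {
  gwas <- data.frame(disease = c("a", "b"), gene = c("G1", "G2"))
  drugs <- data.frame(disease = "a", drug = "d", target = "T1")
  expect_equal(nrow(disease_gene_map(gwas, drugs)), 1)
  empty <- data.frame(disease = character(), drug = character(),
                      target = character())
  expect_equal(nrow(disease_gene_map(gwas, empty)), 0)
})

test_that("missing required columns raise an error naming the column", {
  gwas <- data.frame(disease = "a", gene = "G1")
  bad <- data.frame(disease = "a", drug = "d")
  expect_error(disease_gene_map(gwas, bad), "target")
})

test_that("verified targets are a subset parsed from yes/no style flags", {
  gwas <- data.frame(disease = "a", gene = "G1")
  drugs <- data.frame(disease = rep("a", 3), drug = "d",
                      target = c("T1", "T2", "T3"),
                      verified = c("Yes", "no", "yes"))
  maps <- disease_gene_map(gwas, drugs)
  expect_setequal(maps$verified_targets[[1]], c("T1", "T3"))
  expect_true(all(maps$verified_targets[[1]] %in% maps$target_genes[[1]]))
})

test_that("split_merged turns slash-joined traits into separate diseases", {
  gwas <- data.frame(disease = "Bipolar disorder/Schizophrenia", gene = "G1")
  drugs <- data.frame(disease = c("Bipolar disorder", "Schizophrenia"),
                      drug = "d", target = "T1")
  expect_equal(nrow(disease_gene_map(gwas, drugs)), 0)
  expect_equal(nrow(disease_gene_map(gwas, drugs, split_merged = TRUE)), 2)
})

test_that("disease map round-trips through its TSV form", {
  maps <- make_maps(list(c("A", "B"), "C"), list(c("B", "X"), c("Y", "Z")),
                    list("X", character(0)))
  gw <- withr::local_tempfile(fileext = ".tsv")
  dr <- withr::local_tempfile(fileext = ".tsv")
  write_disease_gene_map(maps, gw, dr)
  back <- load_disease_gene_map(gw, dr)
  expect_equal(nrow(back), nrow(maps))
  ord <- match(tolower(maps$disease), tolower(back$disease))
  expect_identical(back$gwas_genes[ord], maps$gwas_genes)
  expect_identical(back$target_genes[ord], maps$target_genes)
  expect_identical(back$verified_targets[ord], maps$verified_targets)
})

test_that("network loader deduplicates edges and discards self-loops", {
  net <- toy_graph("a", "b", "b", "a", "a", "a")
  expect_equal(igraph::vcount(net), 2)
  expect_equal(igraph::ecount(net), 1)
  expect_equal(igraph::graph_attr(net, "n_self_loops"), 1)
  expect_equal(igraph::graph_attr(net, "n_duplicate_edges"), 1)
})

test_that("network loader handles empty, TSV, SIF and bad files", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_equal(igraph::vcount(load_network(f)), 0)

  writeLines(c("a\tb", "b\tc"), f)
  expect_equal(igraph::ecount(load_network(f)), 2)

  writeLines(c("a\tpp\tb", "b\tpp\tc"), f)
  sif <- load_network(f, format = "sif")
  expect_setequal(igraph::V(sif)$name, c("A", "B", "C"))

  writeLines(c("a\tb", "orphan"), f)
  expect_error(load_network(f), "line 2")
})

test_that("network round-trips through the edge-list writer", {
  net <- toy_graph("a", "b", "b", "c", "c", "d", "a", "d")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  back <- load_network(f)
  expect_identical(network_edges(back), network_edges(net))
})

test_that("generated network loads back with the manifest's counts", {
  gn <- gen_network(500, "preferential_attachment",
                    params = list(edges_per_node = 4), seed = 42)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(gn$network, f)
  back <- load_network(f)
  expect_equal(igraph::vcount(back), gn$manifest$n_nodes)
  expect_equal(igraph::ecount(back), gn$manifest$n_edges)
})

test_that("allele frequency comes from genotype allele counts", {
  # 10 individuals, one site: 2 heterozygotes + 1 homozygous alt -> 4/20
  f <- withr::local_tempfile(fileext = ".vcf")
  gts <- c("0/1", "0/1", "1/1", rep("0/0", 7))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"e\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("S%02d", 1:10)), collapse = "\t"),
    paste(c("1", "100", ".", "A", "G", ".", "PASS",
            "GENE=MYGENE;EFF=nonsynonymous", "GT", gts), collapse = "\t"),
    paste(c("1", "200", ".", "A", "G", ".", "PASS",
            "GENE=MYGENE;EFF=nonsynonymous", "GT", rep("0/0", 10)),
          collapse = "\t"),
    paste(c("1", "300", ".", "A", "G", ".", "PASS",
            "GENE=MYGENE;EFF=synonymous", "GT", gts), collapse = "\t"),
    paste(c("1", "400", ".", "A", "G", ".", "PASS",
            "GENE=MYGENE;EFF=nonsynonymous", "GT", c("./1", rep("0/0", 9))),
          collapse = "\t")
  ), f)
  v <- load_variants(f)
  expect_equal(nrow(v), 3) # synonymous site dropped
  expect_equal(v$allele_frequency[v$pos == 100], 0.2)
  expect_equal(v$allele_frequency[v$pos == 200], 0)
  # half-missing genotype: 1 alt allele over 19 called alleles
  expect_equal(v$alt_allele_count[v$pos == 400], 1L)
  expect_equal(v$total_allele_count[v$pos == 400], 19L)
})

test_that("synthetic VCF frequencies match the generator manifest", {
  genes <- sprintf("GENE%02d", 1:10)
  f <- withr::local_tempfile(fileext = ".vcf")
  gv <- gen_variants(genes, rep(800, 10), rate_per_residue = 0.01,
                     common_fraction = 0.3, n_individuals = 25, seed = 7,
                     path = f)
  v <- load_variants(f)
  expect_equal(nrow(v), gv$manifest$n_variants)
  key <- paste(v$chrom, v$pos)
  gkey <- paste(gv$variants$chrom, gv$variants$pos)
  expect_equal(v$alt_allele_count[match(gkey, key)],
               gv$manifest$alt_allele_counts)
  expect_true(all(v$allele_frequency >= 0 & v$allele_frequency <= 1))
  expect_true(all(v$total_allele_count == 50))
})

test_that("annotation loader validates lengths and keeps missing dN/dS as NA", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    gene = c("a", "b"), protein_length = c(100, 200),
    longest_transcript_length = c(1000, 2000),
    dnds_chimp = c(0.3, NA)
  ), f)
  ann <- load_gene_annotation(f)
  expect_true(is.na(ann$dnds_chimp[2]))
  expect_true(all(is.na(ann$dnds_mouse)))
  readr::write_tsv(tibble::tibble(
    gene = "a", protein_length = -5, longest_transcript_length = 10
  ), f)
  expect_error(load_gene_annotation(f), "positive")
})
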