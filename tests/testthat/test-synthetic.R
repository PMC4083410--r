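test_that("generators are deterministic under a fixed seed", {
  g1 <- gen_network(100, "planted_modules", seed = 5)
  g2 <- gen_network(100, "planted_modules", seed = 5)
  expect_identical(g1$manifest$edges, g2$manifest$edges)

  d1 <- gen_disease(g1$network, 10, 12, seed = 8)
  d2 <- gen_disease(g1$network, 10, 12, seed = 8)
  expect_identical(d1$map, d2$map)

  a1 <- gen_annotation(sprintf("G%03d", 1:50), seed = 2)
  a2 <- gen_annotation(sprintf("G%03d", 1:50), seed = 2)
  expect_identical(a1$annotation, a2$annotation)

  v1 <- gen_variants(c("A", "B"), c(500, 700), seed = 3)
  v2 <- gen_variants(c("A", "B"), c(500, 700), seed = 3)
  expect_identical(v1$variants, v2$variants)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- .Random.seed
  invisible(gen_network(50, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("complete-graph parameters realize all node pairs", {
  g <- gen_network(10, "planted_modules",
                   params = list(n_modules = 1, p_within = 1, p_between = 1),
                   seed = 1)
  expect_equal(g$manifest$n_edges, 45)
  expect_error(
    gen_network(20, "planted_modules", params = list(p_within = 1.5)),
    "probabilities"
  )
  expect_error(gen_network(5), "at least 10")
})

test_that("planted-module edge fractions sit near their expectation", {
  n_mod <- 5; size <- 40
  g <- gen_network(n_mod * size, "planted_modules",
                   params = list(n_modules = n_mod, p_within = 0.2,
                                 p_between = 0.005),
                   seed = 33)
  mod <- rep(seq_len(n_mod), each = size)
  names(mod) <- sprintf("G%05d", seq_len(n_mod * size))
  el <- igraph::as_edgelist(g$network)
  within <- sum(mod[el[, 1]] == mod[el[, 2]])
  between <- nrow(el) - within
  n_within_pairs <- n_mod * choose(size, 2)
  n_between_pairs <- choose(n_mod * size, 2) - n_within_pairs
  # binomial 3-sigma bands around the planted probabilities
  expect_lt(abs(within - 0.2 * n_within_pairs),
            3 * sqrt(n_within_pairs * 0.2 * 0.8))
  expect_lt(abs(between - 0.005 * n_between_pairs),
            3 * sqrt(n_between_pairs * 0.005 * 0.995))
})

test_that("zero proximity bias matches uniform target sampling", {
  gn <- gen_network(300, "preferential_attachment", seed = 3)
  nodes <- igraph::V(gn$network)$name
  # deviation of the sampled targets' mean distance-to-GWAS from the
  # uniform expectation over that simulation's candidate pool
  devs <- vapply(1:200, function(s) {
    d <- gen_disease(gn$network, 12, 20, proximity_bias = 0, seed = 1000 + s)
    gwas <- d$map$gwas_genes[[1]]
    rest <- setdiff(nodes, gwas)
    dmin <- apply(igraph::distances(gn$network, v = gwas, to = rest,
                                    algorithm = "unweighted"), 2, min)
    mean(dmin[d$map$target_genes[[1]]]) - mean(dmin)
  }, numeric(1))
  se <- sd(devs) / sqrt(length(devs))
  expect_lt(abs(mean(devs)), 4 * se)
})

test_that("a very large bias pins all targets next to GWAS genes", {
  gn <- gen_network(300, "preferential_attachment",
                    params = list(edges_per_node = 4), seed = 3)
  d <- gen_disease(gn$network, 20, 10, proximity_bias = 50, seed = 2)
  prof <- distance_to_set(gn$network, d$map$target_genes[[1]],
                          d$map$gwas_genes[[1]])
  expect_true(all(prof$distance <= 1))
})

test_that("disease manifests round-trip the planted sets", {
  gn <- gen_network(100, "planted_modules", seed = 4)
  d <- gen_disease(gn$network, 8, 9, seed = 6)
  expect_identical(d$map$gwas_genes[[1]], d$manifest$gwas_genes)
  expect_identical(d$map$target_genes[[1]], d$manifest$target_genes)
  expect_true(all(d$manifest$verified_targets %in% d$manifest$target_genes))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_manifest(d$manifest, f)
  back <- yaml::read_yaml(f)
  expect_identical(back$gwas_genes, d$manifest$gwas_genes)
})

test_that("zero variant rate yields an empty, well-formed table", {
  v <- gen_variants(c("A", "B"), c(500, 500), rate_per_residue = 0, seed = 1)
  expect_equal(nrow(v$variants), 0)
  expect_true(all(c("gene", "allele_frequency") %in% names(v$variants)))
})

test_that("planted common fraction lands strictly above the 5% threshold", {
  v <- gen_variants(sprintf("G%02d", 1:40), rep(600, 40),
                    rate_per_residue = 0.01, common_fraction = 0.5,
                    n_individuals = 30, seed = 44)
  vv <- v$variants
  expect_true(all(vv$allele_frequency[vv$planted_common] > 0.05))
  expect_true(all(vv$allele_frequency[!vv$planted_common] <= 0.05))
})

test_that("degenerate length variance collapses to the class median", {
  genes <- sprintf("G%02d", 1:30)
  ga <- gen_annotation(genes, classes = list(gwas = genes[1:10]),
                       length_sdlog = 0, seed = 7)
  ann <- ga$annotation
  expect_true(all(ann$longest_transcript_length[ann$class == "gwas"] == 110000))
  expect_true(all(ann$longest_transcript_length[ann$class == "all"] == 60000))
})

test_that("planted dN/dS class means are recovered within 3 sigma", {
  n <- 1000
  genes <- sprintf("G%04d", 1:(2 * n))
  ga <- gen_annotation(genes, classes = list(gwas = genes[1:n]),
                       dnds_chimp_mean = c(all = 0.36, gwas = 0.33),
                       dnds_shape = 2, seed = 19)
  ann <- ga$annotation
  for (cl in c("gwas", "all")) {
    planted <- ifelse(cl == "gwas", 0.33, 0.36)
    x <- ann$dnds_chimp[ann$class == cl]
    se <- planted / sqrt(2) / sqrt(length(x)) # gamma sd = mean/sqrt(shape)
    expect_lt(abs(mean(x) - planted), 3 * se)
  }
})

test_that("generator outputs parse cleanly through every loader", {
  study <- gen_study(seed = 23, n_nodes = 300, n_diseases = 3)
  td <- withr::local_tempdir()
  write_network(study$network, file.path(td, "edges.tsv"))
  net <- load_network(file.path(td, "edges.tsv"))
  expect_equal(igraph::ecount(net), igraph::ecount(study$network))

  write_disease_gene_map(study$maps, file.path(td, "gwas.tsv"),
                         file.path(td, "drugs.tsv"))
  maps <- load_disease_gene_map(file.path(td, "gwas.tsv"),
                                file.path(td, "drugs.tsv"))
  expect_equal(nrow(maps), nrow(study$maps))

  ga <- gen_annotation(igraph::V(study$network)$name, seed = 23)
  readr::write_tsv(ga$annotation[, -2], file.path(td, "ann.tsv"))
  ann <- load_gene_annotation(file.path(td, "ann.tsv"))
  expect_equal(nrow(ann), igraph::vcount(study$network))

  gv <- gen_variants(ann$gene[1:50], ann$protein_length[1:50],
                     rate_per_residue = 0.02, n_individuals = 10,
                     seed = 23, path = file.path(td, "v.vcf"))
  v <- load_variants(file.path(td, "v.vcf"))
  expect_equal(nrow(v), nrow(gv$variants))
})
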