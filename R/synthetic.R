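#' @name synthetic
#' @title Seeded generators for synthetic study data
#' @description
#' The generators emulate the statistical structure the analyses assume —
#' a modular or scale-free protein network, disease gene sets whose
#' drug targets sit close to the GWAS genes, variant tables with a planted
#' non-synonymous SNP density, and annotations with planted transcript
#' length and dN/dS distributions — so every pipeline stage can be tested
#' without external downloads. Each generator is fully deterministic
#' under its seed and returns a manifest recording what was planted.
NULL

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic interaction network
#'
#' `"preferential_attachment"` grows a scale-free graph (hubs emerge, as
#' in protein networks); `"planted_modules"` draws a stochastic block
#' model with dense modules and sparse between-module edges.
#'
#' @param n_nodes Number of genes (>= 10).
#' @param model `"preferential_attachment"` or `"planted_modules"`.
#' @param params For preferential attachment: `edges_per_node` (default
#'   3). For planted modules: `n_modules` (default 5), `p_within`
#'   (default 0.2), `p_between` (default 0.005).
#' @param seed Integer seed.
#' @return A list: `network` (igraph, vertices named `G00001`...) and
#'   `manifest` (seed, model, params, realized node/edge counts, exact
#'   edge list).
#' @export
gen_network <- function(n_nodes,
                        model = c("preferential_attachment", "planted_modules"),
                        params = list(), seed = 1) {
  model <- match.arg(model)
  if (n_nodes < 10) abort("n_nodes must be at least 10")
  g <- with_seed(seed, {
    if (model == "preferential_attachment") {
      epn <- params$edges_per_node %||% 3
      if (epn >= n_nodes) abort("edges_per_node must be below n_nodes")
      igraph::sample_pa(n_nodes, m = epn, directed = FALSE)
    } else {
      k <- params$n_modules %||% 5
      p_within <- params$p_within %||% 0.2
      p_between <- params$p_between %||% 0.005
      if (p_within > 1 || p_between > 1) {
        abort("edge probabilities must be at most 1 (more edges than pairs)")
      }
      sizes <- rep(n_nodes %/% k, k)
      sizes[seq_len(n_nodes %% k)] <- sizes[seq_len(n_nodes %% k)] + 1
      pm <- matrix(p_between, k, k)
      diag(pm) <- p_within
      igraph::sample_sbm(n_nodes, pref.matrix = pm, block.sizes = sizes)
    }
  })
  igraph::V(g)$name <- sprintf("G%05d", seq_len(n_nodes))
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g)
  list(
    network = g,
    manifest = list(
      seed = seed, model = model, params = params,
      n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
      module = if (model == "planted_modules") {
        rep(seq_len(params$n_modules %||% 5),
            times = {
              k <- params$n_modules %||% 5
              s <- rep(n_nodes %/% k, k)
              s[seq_len(n_nodes %% k)] <- s[seq_len(n_nodes %% k)] + 1
              s
            })
      } else NULL,
      edges = tibble(from = el[, 1], to = el[, 2])
    )
  )
}

#' Generate a disease with proximity-biased drug targets
#'
#' GWAS genes are seeded in one network region (the nodes closest to a
#' random start node); drug targets are then sampled with probability
#' weight `exp(-proximity_bias * distance-to-nearest-GWAS-gene)`, so
#' `proximity_bias = 0` is uniform sampling and large bias pulls every
#' target into the immediate GWAS neighborhood.
#'
#' @param network An igraph interaction network.
#' @param n_gwas,n_targets Set sizes (each at most the node count).
#' @param proximity_bias Non-negative bias strength.
#' @param seed Integer seed.
#' @param disease Disease label.
#' @param verified_fraction Fraction of targets flagged as verified.
#' @return A list: `map` (one-row `disease_gene_map` tibble) and
#'   `manifest` (planted sets and parameters).
#' @export
gen_disease <- function(network, n_gwas, n_targets, proximity_bias = 4,
                        seed = 1, disease = "synthetic disease",
                        verified_fraction = 0.5) {
  nodes <- igraph::V(network)$name
  if (n_gwas + n_targets > length(nodes)) {
    abort("n_gwas + n_targets exceeds the node count")
  }
  sets <- with_seed(seed, {
    start <- sample(nodes, 1)
    d0 <- igraph::distances(network, v = start, algorithm = "unweighted")[1, ]
    d0[!is.finite(d0)] <- max(d0[is.finite(d0)]) + 1
    gwas <- nodes[order(d0, runif(length(nodes)))][seq_len(n_gwas)]
    rest <- setdiff(nodes, gwas)
    dg <- igraph::distances(network, v = gwas, to = rest,
                            algorithm = "unweighted")
    d2g <- apply(dg, 2, min)
    d2g[!is.finite(d2g)] <- max(d2g[is.finite(d2g)], 1) + 1
    # shift by the minimum so large biases never underflow every weight
    w <- exp(-proximity_bias * (d2g - min(d2g)))
    targets <- sample(rest, n_targets, prob = w)
    verified <- sort(sample(targets, round(verified_fraction * n_targets)))
    list(gwas = sort(gwas), targets = sort(targets), verified = verified)
  })
  map <- tibble(
    disease = disease,
    gwas_genes = list(sets$gwas),
    drugs = list(paste0("drug_", seq_len(max(1, ceiling(n_targets / 3))))),
    target_genes = list(sets$targets),
    verified_targets = list(sets$verified),
    m = length(sets$gwas),
    n = length(sets$targets)
  )
  class(map) <- c("disease_gene_map", class(map))
  list(
    map = map,
    manifest = list(
      seed = seed, disease = disease, n_gwas = n_gwas,
      n_targets = n_targets, proximity_bias = proximity_bias,
      gwas_genes = sets$gwas, target_genes = sets$targets,
      verified_targets = sets$verified
    )
  )
}

#' Generate a collection of synthetic diseases
#'
#' Convenience wrapper around [gen_disease()] drawing per-disease set
#' sizes uniformly from the given ranges, with one derived seed per
#' disease.
#'
#' @param network An igraph interaction network.
#' @param n_diseases Number of diseases.
#' @param n_gwas_range,n_targets_range Inclusive ranges for set sizes.
#' @inheritParams gen_disease
#' @return A list: `maps` (multi-row `disease_gene_map`) and `manifests`.
#' @export
gen_disease_collection <- function(network, n_diseases = 30,
                                   n_gwas_range = c(10, 60),
                                   n_targets_range = c(10, 50),
                                   proximity_bias = 4, seed = 1) {
  sizes <- with_seed(seed, list(
    gwas = sample(n_gwas_range[1]:n_gwas_range[2], n_diseases, replace = TRUE),
    targets = sample(n_targets_range[1]:n_targets_range[2], n_diseases,
                     replace = TRUE)
  ))
  out <- map(seq_len(n_diseases), function(i) {
    gen_disease(network, sizes$gwas[i], sizes$targets[i],
                proximity_bias = proximity_bias,
                seed = seed * 1000L + i,
                disease = sprintf("disease_%02d", i))
  })
  maps <- bind_rows(map(out, "map"))
  class(maps) <- c("disease_gene_map", class(maps))
  list(maps = maps, manifests = map(out, "manifest"))
}

#' Generate a non-synonymous variant table with planted density
#'
#' Per-gene variant counts are Poisson with mean `rate_per_residue *
#' protein_length`. Each variant is common (allele frequency strictly
#' above 5%) with probability `common_fraction`; alternate allele counts
#' are drawn uniformly from the corresponding frequency band and
#' distributed over `2 * n_individuals` chromosomes, so the loader's
#' genotype-derived frequencies reproduce the planted counts exactly.
#'
#' @param genes Character vector of gene IDs.
#' @param protein_lengths Residue counts, parallel to `genes`.
#' @param rate_per_residue Non-synonymous SNPs per residue.
#' @param common_fraction Fraction of variants planted above the 5%
#'   frequency threshold.
#' @param n_individuals Diploid sample count.
#' @param seed Integer seed.
#' @param path Optional path; when given, a minimal VCF 4.2 file with
#'   per-sample genotypes is written there.
#' @return A list: `variants` (tibble in [load_variants()] layout plus a
#'   `planted_common` flag), `manifest`, and `path`.
#' @export
gen_variants <- function(genes, protein_lengths, rate_per_residue = 0.0171,
                         common_fraction = 0.13, n_individuals = 60,
                         seed = 1, path = NULL) {
  stopifnot(length(genes) == length(protein_lengths),
            rate_per_residue >= 0, common_fraction >= 0,
            common_fraction <= 1)
  n_chrom <- 2L * n_individuals
  cut_alt <- floor(0.05 * n_chrom) # largest alt count with frequency <= 5%
  if (cut_alt + 1 > n_chrom %/% 2) abort("n_individuals too small to plant common variants")
  res <- with_seed(seed, {
    counts <- rpois(length(genes), rate_per_residue * protein_lengths)
    v <- tibble(
      gene = rep(normalize_gene_id(genes), counts),
      gene_idx = rep(seq_along(genes), counts)
    )
    if (nrow(v) > 0) {
      v <- v %>%
        group_by(.data$gene_idx) %>%
        mutate(within = dplyr::row_number()) %>%
        ungroup() %>%
        mutate(
          chrom = "1",
          pos = .data$gene_idx * 100000L + .data$within,
          ref = "A", alt = "G",
          planted_common = runif(n()) < common_fraction,
          alt_allele_count = ifelse(
            .data$planted_common,
            sample((cut_alt + 1):(n_chrom %/% 2), n(), replace = TRUE),
            sample(seq_len(max(cut_alt, 1)), n(), replace = TRUE)
          ),
          total_allele_count = n_chrom,
          allele_frequency = .data$alt_allele_count / n_chrom
        )
    }
    # genotype strings are only materialized when a VCF is written
    gt <- if (!is.null(path) && nrow(v) > 0) {
      t(vapply(v$alt_allele_count, function(ac) {
        carriers <- sample.int(n_chrom, ac)
        a1 <- as.integer(seq(1, n_chrom, by = 2) %in% carriers)
        a2 <- as.integer(seq(2, n_chrom, by = 2) %in% carriers)
        paste0(a1, "/", a2)
      }, character(n_individuals)))
    } else {
      matrix(character(0), nrow = 0, ncol = n_individuals)
    }
    list(v = v, gt = gt)
  })
  variants <- if (nrow(res$v) > 0) {
    select(res$v, -dplyr::any_of(c("gene_idx", "within")))
  } else {
    mutate(empty_variant_table(), planted_common = logical(0))
  }
  if (!is.null(path)) {
    write_minimal_vcf(res$v, res$gt, n_individuals, path)
  }
  list(
    variants = variants,
    manifest = list(
      seed = seed, rate_per_residue = rate_per_residue,
      common_fraction = common_fraction, n_individuals = n_individuals,
      n_variants = nrow(variants),
      alt_allele_counts = variants$alt_allele_count
    ),
    path = path
  )
}

write_minimal_vcf <- function(v, gt, n_individuals, path) {
  samples <- sprintf("S%03d", seq_len(n_individuals))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene identifier\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Consequence annotation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- character(0)
  if (nrow(v) > 0) {
    info <- sprintf("GENE=%s;EFF=nonsynonymous", v$gene)
    left <- cbind(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT")
    body <- apply(cbind(left, gt), 1, paste, collapse = "\t")
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Generate a gene annotation table with planted class distributions
#'
#' Longest transcript lengths are log-normal with a per-class median
#' (GWAS genes about twice as long as targets by default); protein
#' lengths are log-normal; dN/dS ratios are gamma-distributed with
#' per-class means (drug targets below GWAS genes below the background,
#' i.e. stronger purifying selection). A gene belonging to several
#' classes takes the first matching class in list order; all remaining
#' genes form the background class `"all"`.
#'
#' @param genes Character vector of gene IDs.
#' @param classes Named list of gene-ID vectors (e.g.
#'   `list(gwas = ..., drug_target = ...)`).
#' @param length_median Named per-class medians (bases) for the longest
#'   transcript; must include `"all"`.
#' @param length_sdlog Log-scale SD of transcript lengths (0 makes every
#'   length equal its class median).
#' @param protein_median,protein_sdlog Log-normal parameters for protein
#'   length (residues).
#' @param dnds_chimp_mean,dnds_mouse_mean Named per-class mean dN/dS.
#' @param dnds_shape Gamma shape for dN/dS draws.
#' @param seed Integer seed.
#' @return A list: `annotation` (tibble in [load_gene_annotation()]
#'   layout plus a `class` column) and `manifest`.
#' @export
gen_annotation <- function(genes, classes = list(),
                           length_median = c(all = 60000, gwas = 110000,
                                             drug_target = 60000),
                           length_sdlog = 1,
                           protein_median = 450, protein_sdlog = 0.5,
                           dnds_chimp_mean = c(all = 0.44, gwas = 0.36,
                                               drug_target = 0.33),
                           dnds_mouse_mean = c(all = 0.22, gwas = 0.19,
                                               drug_target = 0.18),
                           dnds_shape = 2, seed = 1) {
  genes <- normalize_gene_id(genes)
  cls <- rep("all", length(genes))
  for (nm in rev(names(classes))) {
    cls[genes %in% normalize_gene_id(classes[[nm]])] <- nm
  }
  param_of <- function(p, class) unname(p[ifelse(class %in% names(p), class, "all")])
  ann <- with_seed(seed, tibble(
    gene = genes,
    class = cls,
    protein_length = pmax(
      30, round(rlnorm(length(genes), log(protein_median), protein_sdlog))
    ),
    longest_transcript_length = pmax(
      200,
      round(rlnorm(length(genes), log(param_of(length_median, cls)),
                   length_sdlog))
    ),
    dnds_mouse = rgamma(length(genes), shape = dnds_shape,
                        scale = param_of(dnds_mouse_mean, cls) / dnds_shape),
    dnds_chimp = rgamma(length(genes), shape = dnds_shape,
                        scale = param_of(dnds_chimp_mean, cls) / dnds_shape)
  ))
  list(
    annotation = ann,
    manifest = list(
      seed = seed, classes = map(classes, normalize_gene_id),
      length_median = length_median, length_sdlog = length_sdlog,
      protein_median = protein_median, protein_sdlog = protein_sdlog,
      dnds_chimp_mean = dnds_chimp_mean, dnds_mouse_mean = dnds_mouse_mean,
      dnds_shape = dnds_shape
    )
  )
}

#' Generate the default synthetic study
#'
#' One call producing the package's reference simulation conditions: a
#' 2000-gene planted-module network (8 modules, within-module edge
#' probability 0.03, between-module 0.0015, mean degree about 10 so
#' typical distances span 1-4 hops as on a sparse protein network) and 30
#' diseases with proximity bias 3, whose pooled drug targets form a
#' candidate universe of several hundred genes.
#'
#' @param seed Integer seed.
#' @param n_nodes,n_diseases Scale overrides.
#' @param proximity_bias Target placement bias (see [gen_disease()]).
#' @return A list: `network`, `maps`, `universe` (all target genes), and
#'   the generator `manifests`.
#' @export
gen_study <- function(seed = 1, n_nodes = 2000, n_diseases = 30,
                      proximity_bias = 4) {
  net <- gen_network(
    n_nodes, "planted_modules",
    params = list(n_modules = 8, p_within = 0.03, p_between = 0.0015),
    seed = seed
  )
  dis <- gen_disease_collection(net$network, n_diseases,
                                proximity_bias = proximity_bias, seed = seed)
  list(
    network = net$network,
    maps = dis$maps,
    universe = sort(unique(unlist(dis$maps$target_genes))),
    manifests = c(list(network = net$manifest), dis$manifests)
  )
}

#' Serialize a generator manifest as YAML
#'
#' @param manifest A manifest list from any generator.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  serializable <- rapply(manifest, function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }, classes = "ANY", how = "replace")
  yaml::write_yaml(serializable, path)
  invisible(path)
}
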