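#' Assemble a pipeline run configuration
#'
#' @param gwas,drugs,network,variants,annotation,loci,alias Input file
#'   paths (TSV / VCF / edge list); all optional — stages lacking their
#'   inputs are skipped. With `simulate = TRUE` the inputs are generated
#'   instead.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stage names to run, from
#'   `c("overlap", "variants", "network", "repurpose")`.
#' @param simulate Generate synthetic inputs at default scale instead of
#'   reading files.
#' @param seed Integer seed recorded in all outputs and driving every
#'   stochastic component.
#' @param genome_size Genome size for the overlap null model.
#' @param common_threshold Allele-frequency cutoff for common SNPs.
#' @param min_targets,min_gwas Eligibility cutoffs for the classifier.
#' @param probability_threshold Repurposing candidate cutoff.
#' @param n_nodes,n_diseases Synthetic scale (used when `simulate`).
#' @return A `run_config` list.
#' @export
run_config <- function(gwas = NULL, drugs = NULL, network = NULL,
                       variants = NULL, annotation = NULL, loci = NULL,
                       alias = NULL, out_dir = tempfile("targetnet_run_"),
                       stages = c("overlap", "variants", "network",
                                  "repurpose"),
                       simulate = FALSE, seed = 1, genome_size = 20000,
                       common_threshold = 0.05, min_targets = 10,
                       min_gwas = 10, probability_threshold = 0.5,
                       n_nodes = 2000, n_diseases = 30) {
  stopifnot(genome_size > 0, common_threshold >= 0, common_threshold < 1,
            probability_threshold >= 0, probability_threshold <= 1,
            min_targets >= 0, min_gwas >= 0)
  structure(
    list(gwas = gwas, drugs = drugs, network = network, variants = variants,
         annotation = annotation, loci = loci, alias = alias,
         out_dir = out_dir, stages = stages, simulate = simulate,
         seed = as.integer(seed), genome_size = genome_size,
         common_threshold = common_threshold, min_targets = min_targets,
         min_gwas = min_gwas,
         probability_threshold = probability_threshold,
         n_nodes = n_nodes, n_diseases = n_diseases),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order — per-disease overlap with the
#' random null model, variant / length / dN/dS contrasts, network
#' proximity statistics, and the per-disease repurposing classifier —
#' writing one TSV per result, the resolved configuration, and a
#' markdown summary report into `config$out_dir`. Reruns with the same
#' configuration and seed reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  yaml::write_yaml(unclass(config), out("config.yaml"))
  results <- list()
  report <- c("# targetnet pipeline report", "",
              sprintf("seed: %d", config$seed), "")
  stage <- "load"
  tryCatch({
    inputs <- pipeline_inputs(config)
    results$inputs <- inputs

    if ("overlap" %in% config$stages && !is.null(inputs$maps)) {
      stage <- "overlap"
      ov <- compute_overlap(inputs$maps, genome_size = config$genome_size)
      readr::write_tsv(tidy(ov), out("overlap_per_disease.tsv"))
      readr::write_tsv(glance(ov), out("overlap_summary.tsv"))
      g <- glance(ov)
      report <- c(report, "## Overlap", sprintf(
        "- observed total %d (mean %.2f per disease), expected %.2f, unique overlapping genes %d",
        g$total_observed, g$mean_observed, g$total_expected,
        g$unique_overlapping_genes
      ), "")
      if (!is.null(inputs$loci)) {
        exp_ov <- compute_overlap(
          expand_candidates_by_locus(inputs$maps, inputs$loci),
          genome_size = config$genome_size
        )
        readr::write_tsv(tidy(exp_ov), out("overlap_locus_expanded.tsv"))
      }
      results$overlap <- ov
    }

    if ("variants" %in% config$stages && !is.null(inputs$annotation) &&
        !is.null(inputs$maps)) {
      stage <- "variants"
      gwas_all <- unique(unlist(inputs$maps$gwas_genes))
      targ_all <- unique(unlist(inputs$maps$target_genes))
      if (!is.null(inputs$variants)) {
        dens <- list(
          drug_target = snp_density(inputs$variants, inputs$annotation,
                                    targ_all, config$common_threshold),
          gwas = snp_density(inputs$variants, inputs$annotation,
                             gwas_all, config$common_threshold),
          all = snp_density(inputs$variants, inputs$annotation,
                            inputs$annotation$gene, config$common_threshold)
        )
        dens_tab <- bind_rows(imap(dens, ~ mutate(glance(.x), class = .y))) %>%
          select("class", dplyr::everything())
        dens_test <- compare_gene_classes(
          dens$drug_target$density_common, dens$gwas$density_common
        )
        readr::write_tsv(dens_tab, out("snp_density.tsv"))
        readr::write_tsv(dens_test, out("snp_density_test.tsv"))
        report <- c(report, "## SNP density (per residue)", sprintf(
          "- common nsSNP density: targets %.5f vs GWAS %.5f (rank-sum p = %.3g)",
          glance(dens$drug_target)$density_common_nonsyn,
          glance(dens$gwas)$density_common_nonsyn, dens_test$p_value
        ), "")
        results$density <- dens
      }
      lc <- longest_transcript_contrast(inputs$annotation, gwas_all, targ_all,
                                        labels = c("gwas", "drug_target"))
      readr::write_tsv(glance(lc), out("transcript_length.tsv"))
      dn <- dnds_contrast(inputs$annotation,
                          list(gwas = gwas_all, drug_target = targ_all),
                          ortholog = "chimp")
      readr::write_tsv(dn, out("dnds_chimp.tsv"))
      report <- c(report, "## Length and selection", sprintf(
        "- median transcript length ratio (GWAS/targets) %.2f (p = %.3g)",
        lc$median_ratio, lc$test$p_value
      ), sprintf(
        "- mean chimp dN/dS: %s",
        paste(sprintf("%s %.2f", dn$class, dn$mean_dnds), collapse = ", ")
      ), "")
      results$length <- lc
      results$dnds <- dn
    }

    if ("network" %in% config$stages && !is.null(inputs$network) &&
        !is.null(inputs$maps)) {
      stage <- "network"
      gwas_all <- unique(unlist(inputs$maps$gwas_genes))
      targ_all <- unique(unlist(inputs$maps$target_genes))
      prof_gwas <- distance_to_set(inputs$network, gwas_all, targ_all)
      prof_all <- distance_to_set(inputs$network,
                                  reference_set = targ_all)
      readr::write_tsv(distance_histogram(prof_gwas),
                       out("distance_gwas_to_targets.tsv"))
      readr::write_tsv(distance_histogram(prof_all),
                       out("distance_all_to_targets.tsv"))
      enr <- bind_rows(
        neighbor_enrichment(inputs$network, gwas_all, targ_all, order = 1),
        neighbor_enrichment(inputs$network, gwas_all, targ_all, order = 2)
      )
      readr::write_tsv(enr, out("neighbor_enrichment.tsv"))
      deg <- degree_contrast(inputs$network, targ_all)
      readr::write_tsv(deg$test, out("degree_contrast.tsv"))
      report <- c(report, "## Network proximity", sprintf(
        "- mean distance to nearest target: GWAS genes %.2f vs all genes %.2f",
        glance(prof_gwas)$mean_distance, glance(prof_all)$mean_distance
      ), sprintf(
        "- first/second-neighbor fold enrichment of targets: %.2f / %.2f",
        enr$fold_enrichment[1], enr$fold_enrichment[2]
      ), "")
      results$proximity <- list(gwas = prof_gwas, all = prof_all,
                                enrichment = enr, degree = deg)
    }

    if ("repurpose" %in% config$stages && !is.null(inputs$network) &&
        !is.null(inputs$maps)) {
      stage <- "repurpose"
      elig <- eligible_diseases(inputs$maps, inputs$network,
                                config$min_targets, config$min_gwas)
      readr::write_tsv(elig, out("eligible_diseases.tsv"))
      universe <- unique(unlist(inputs$maps$target_genes))
      target_sets <- setNames(inputs$maps$target_genes, inputs$maps$disease)
      met <- list(); cands <- list()
      for (dz in elig$disease[elig$eligible]) {
        row <- which(inputs$maps$disease == dz)[1]
        fm <- build_feature_matrix(
          inputs$network, inputs$maps$gwas_genes[[row]], universe,
          intersect(inputs$maps$target_genes[[row]],
                    igraph::V(inputs$network)$name)
        )
        cv <- metacost_train_evaluate(
          fm, rf_config(seed = config$seed + row)
        )
        met[[dz]] <- mutate(glance(cv), disease = dz)
        cands[[dz]] <- mutate(
          rank_repurposing_candidates(cv, config$probability_threshold,
                                      target_sets[names(target_sets) != dz]),
          disease = dz
        )
      }
      if (length(met) > 0) {
        met_tab <- bind_rows(met) %>% select("disease", dplyr::everything())
        cand_tab <- bind_rows(cands) %>%
          select("disease", dplyr::everything())
        readr::write_tsv(met_tab, out("classifier_metrics.tsv"))
        readr::write_tsv(cand_tab, out("repurposing_candidates.tsv"))
        report <- c(report, "## Repurposing classifier", sprintf(
          "- %d eligible diseases; mean ROC area %.3f; %d candidates listed",
          nrow(met_tab), mean(met_tab$roc_area), nrow(cand_tab)
        ), "")
        results$classifier <- list(metrics = met_tab, candidates = cand_tab)
      }
    }
  }, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)), parent = e)
  })
  readr::write_lines(report, out("report.md"))
  invisible(results)
}

# load real inputs or generate synthetic ones at the configured scale
pipeline_inputs <- function(config) {
  if (config$simulate) {
    study <- gen_study(config$seed, n_nodes = config$n_nodes,
                       n_diseases = config$n_diseases)
    net <- list(network = study$network)
    dis <- list(maps = study$maps)
    genes <- igraph::V(net$network)$name
    ann <- gen_annotation(
      genes,
      classes = list(gwas = unique(unlist(dis$maps$gwas_genes)),
                     drug_target = unique(unlist(dis$maps$target_genes))),
      seed = config$seed
    )
    vcf_path <- file.path(config$out_dir, "synthetic_variants.vcf")
    vars <- gen_variants(
      ann$annotation$gene, ann$annotation$protein_length,
      n_individuals = 30, seed = config$seed, path = vcf_path
    )
    return(list(maps = dis$maps, network = net$network,
                annotation = ann$annotation, variants = vars$variants,
                loci = NULL))
  }
  alias <- if (!is.null(config$alias)) load_alias_table(config$alias) else NULL
  list(
    maps = if (!is.null(config$gwas) && !is.null(config$drugs)) {
      load_disease_gene_map(config$gwas, config$drugs)
    },
    network = if (!is.null(config$network)) {
      load_network(config$network, alias = alias)
    },
    annotation = if (!is.null(config$annotation)) {
      load_gene_annotation(config$annotation, alias = alias)
    },
    variants = if (!is.null(config$variants)) {
      load_variants(config$variants, alias = alias)
    },
    loci = if (!is.null(config$loci)) load_locus_map(config$loci, alias)
  )
}
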