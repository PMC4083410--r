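# Shared fixtures and independent oracles used across the suite.

# small undirected graph from a two-column matrix of endpoint labels
toy_graph <- function(...) {
  edges <- matrix(c(...), ncol = 2, byrow = TRUE)
  as_interaction_network(as.data.frame(edges))
}

# Erdos-Renyi test graph with named nodes, connected-ish for small p
random_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  g
}

# minimal disease map from plain gene-set lists
make_maps <- function(gwas_sets, target_sets, verified_sets = NULL) {
  nd <- length(gwas_sets)
  verified_sets <- verified_sets %||% rep(list(character(0)), nd)
  out <- tibble::tibble(
    disease = sprintf("disease %d", seq_len(nd)),
    gwas_genes = lapply(gwas_sets, normalize_gene_id),
    drugs = rep(list("drug_1"), nd),
    target_genes = lapply(target_sets, normalize_gene_id),
    verified_targets = lapply(verified_sets, normalize_gene_id),
    m = lengths(gwas_sets),
    n = lengths(target_sets)
  )
  structure(out, class = c("disease_gene_map", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent rank-sum oracle -------------------------------------------
# Exhaustive-enumeration Mann-Whitney: every assignment of the pooled ranks
# to sample a is equally likely under the null. Returns the W statistic (as
# reported by wilcox.test) and the exact two-sided p-value
# 2 * min(P(W <= w), P(W >= w)) capped at 1. Assumes no ties.
ranksum_enumerate <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  all_w <- apply(utils::combn(na + length(b), na), 2, function(idx) {
    sum(sort(r)[idx]) - na * (na + 1) / 2
  })
  p <- 2 * min(mean(all_w <= w_obs), mean(all_w >= w_obs))
  list(statistic = w_obs, p_value = min(1, p))
}

# --- brute-force Jaccard oracle --------------------------------------------
jaccard_enumerate <- function(network, a, b) {
  na <- igraph::neighbors(network, a)$name
  nb <- igraph::neighbors(network, b)$name
  u <- union(na, nb)
  if (length(u) == 0) return(0)
  length(intersect(na, nb)) / length(u)
}

# --- brute-force linker oracle (one-intermediate case) ---------------------
# enumerate simple paths of length <= max_len between all pairs of kept
# genes and collect their internal nodes
linker_enumerate <- function(network, kept, max_len) {
  kept <- intersect(kept, igraph::V(network)$name)
  inter <- character(0)
  for (u in kept) {
    ps <- igraph::all_simple_paths(network, from = u, to = setdiff(kept, u),
                                   cutoff = max_len)
    for (p in ps) {
      nm <- p$name
      inter <- union(inter, setdiff(nm[-c(1, length(nm))], kept))
    }
  }
  sort(inter)
}
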