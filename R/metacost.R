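#' Random-forest configuration for drug-target prediction
#'
#' Defaults follow the study design: `I = 50` trees, `K = floor(sqrt(3 +
#' N))` features per split, stratified 10-fold cross-validation, and a
#' false-negative cost equal to the negative/positive class ratio so the
#' scarce known-target class is protected.
#'
#' @param n_trees Number of trees (I).
#' @param mtry Features per split (K); `NULL` = `floor(sqrt(p))` with p
#'   the feature count.
#' @param cost_ratio Cost of a false negative relative to a false
#'   positive; `NULL` = `#negatives / #positives` of the supplied matrix.
#' @param folds Cross-validation folds.
#' @param bags Bootstrap bags used for the cost-sensitive relabeling.
#' @param seed Integer seed driving folds, bags and forests.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 50, mtry = NULL, cost_ratio = NULL,
                      folds = 10, bags = 10, seed = 1) {
  stopifnot(n_trees >= 1, folds >= 2, bags >= 1)
  structure(
    list(n_trees = n_trees, mtry = mtry, cost_ratio = cost_ratio,
         folds = folds, bags = bags, seed = as.integer(seed)),
    class = "rf_config"
  )
}

#' Cost-sensitive random forest with cross-validated evaluation
#'
#' Trains a per-disease classifier on the network feature matrix under
#' stratified k-fold cross-validation. Within each training fold a
#' MetaCost-style relabeling is applied first: class probabilities are
#' estimated by bagging (bootstrap resamples of the training fold, each
#' fitted with the same forest learner), and every training gene is
#' relabeled to the class with minimum expected cost under the cost
#' matrix (false negative = `cost_ratio`, false positive = 1) — i.e.
#' relabeled positive when `P(positive) > 1 / (1 + cost_ratio)`. A final
#' forest with `n_trees` trees and `mtry` features per split is fitted on
#' the relabeled fold, and held-out genes receive its class probability.
#' Out-of-fold probabilities across folds yield the evaluation metrics.
#'
#' @param matrix A `feature_matrix` (see [build_feature_matrix()]) with
#'   at least 2 positive and 2 negative labels.
#' @param config An [rf_config()].
#' @return A `target_rf_cv` object. [glance()] returns the metric row
#'   (`true_positive_rate`, `false_positive_rate`, `precision`, `recall`,
#'   `roc_area`, `f_measure`); [tidy()] the per-gene out-of-fold
#'   probabilities; [autoplot()] the ROC curve.
#' @export
metacost_train_evaluate <- function(matrix, config = rf_config()) {
  stopifnot(inherits(matrix, "feature_matrix") || is.data.frame(matrix))
  # canonical row order: results are invariant to the caller's row order
  matrix <- matrix[order(matrix$gene), ]
  y <- matrix$label
  if (sum(y) < 2 || sum(!y) < 2) {
    abort("need at least 2 positive and 2 negative genes")
  }
  feats <- as.data.frame(matrix[, feature_columns(matrix)])
  p <- ncol(feats)
  mtry <- config$mtry %||% max(1, floor(sqrt(p)))
  cost_ratio <- config$cost_ratio %||% (sum(!y) / sum(y))
  relabel_cut <- 1 / (1 + cost_ratio)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  fold <- stratified_folds(y, config$folds)
  if (any(vapply(seq_len(config$folds),
                 function(k) sum(y[fold != k]) == 0, logical(1)))) {
    abort("stratification failed: a training fold has no positive genes")
  }

  prob <- rep(NA_real_, length(y))
  for (k in sort(unique(fold))) {
    tr <- which(fold != k)
    te <- which(fold == k)
    p_pos <- bagged_probabilities(feats[tr, , drop = FALSE], y[tr],
                                  config, mtry)
    y_cost <- p_pos > relabel_cut
    prob[te] <- forest_probability(feats[tr, , drop = FALSE], y_cost,
                                   feats[te, , drop = FALSE], config, mtry)
  }

  metrics <- classification_metrics(y, prob)
  structure(
    list(
      metrics = metrics,
      predictions = tibble(gene = matrix$gene, label = y,
                           probability = prob, fold = fold),
      config = config,
      mtry = mtry,
      cost_ratio = cost_ratio
    ),
    class = "target_rf_cv"
  )
}

# deterministic-given-seed stratified fold assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# mean positive-class probability across bootstrap-bagged forests
bagged_probabilities <- function(x, y, config, mtry) {
  n <- nrow(x)
  acc <- rep(0, n)
  for (b in seq_len(config$bags)) {
    idx <- sample.int(n, n, replace = TRUE)
    acc <- acc + forest_probability(x[idx, , drop = FALSE], y[idx], x,
                                    config, mtry)
  }
  acc / config$bags
}

# positive-class probability from one forest; degenerate one-class
# training data yields that class's constant probability
forest_probability <- function(x_train, y_train, x_new, config, mtry) {
  if (length(unique(y_train)) < 2) {
    return(rep(as.numeric(y_train[1]), nrow(x_new)))
  }
  fit <- randomForest::randomForest(
    x = x_train, y = factor(y_train, levels = c(FALSE, TRUE)),
    ntree = config$n_trees, mtry = min(mtry, ncol(x_train))
  )
  unname(stats::predict(fit, x_new, type = "prob")[, "TRUE"])
}

# confusion metrics at probability 0.5 plus rank-based ROC area
classification_metrics <- function(label, prob, cutoff = 0.5) {
  pred <- prob >= cutoff
  tp <- sum(pred & label); fp <- sum(pred & !label)
  fn <- sum(!pred & label); tn <- sum(!pred & !label)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (prec + tpr > 0) 2 * prec * tpr / (prec + tpr) else 0
  roc <- as.numeric(pROC::auc(
    response = label, predictor = prob, levels = c(FALSE, TRUE),
    direction = "<", quiet = TRUE
  ))
  tibble(
    true_positive_rate = tpr, false_positive_rate = fpr,
    precision = prec, recall = tpr, roc_area = roc, f_measure = f,
    n_positive = tp + fn, n_negative = fp + tn
  )
}

#' @rdname metacost_train_evaluate
#' @param x,object A `target_rf_cv`.
#' @param ... Unused.
#' @method glance target_rf_cv
#' @export
glance.target_rf_cv <- function(x, ...) x$metrics

#' @rdname metacost_train_evaluate
#' @method tidy target_rf_cv
#' @export
tidy.target_rf_cv <- function(x, ...) x$predictions

#' @export
print.target_rf_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Cost-sensitive random forest CV (%d folds, %d trees, mtry %d, cost ratio %.1f)\n",
    x$config$folds, x$config$n_trees, x$mtry, x$cost_ratio
  ))
  cat(sprintf(
    "  TP rate %.3f  FP rate %.3f  precision %.3f  ROC area %.3f  F %.3f\n",
    m$true_positive_rate, m$false_positive_rate, m$precision, m$roc_area,
    m$f_measure
  ))
  invisible(x)
}

#' @rdname metacost_train_evaluate
#' @method autoplot target_rf_cv
#' @export
autoplot.target_rf_cv <- function(object, ...) {
  r <- pROC::roc(response = object$predictions$label,
                 predictor = object$predictions$probability,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  df <- tibble(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Rank label-negative genes as repurposing candidates
#'
#' "False positives" of the disease classifier — genes that are drug
#' targets for other diseases but not for the focal one, yet receive a
#' high target probability — are the repurposing candidates. Candidates
#' at or above the probability threshold are sorted by descending
#' probability, ties broken by gene ID.
#'
#' @param cv A `target_rf_cv` from [metacost_train_evaluate()].
#' @param threshold Minimum out-of-fold probability.
#' @param target_diseases Optional named list (disease -> gene IDs) used
#'   to annotate which other diseases already target each candidate.
#' @return A tibble: `gene`, `probability`, `already_target_for`.
#' @export
rank_repurposing_candidates <- function(cv, threshold = 0.5,
                                        target_diseases = NULL) {
  cand <- cv$predictions %>%
    filter(!.data$label, .data$probability >= threshold) %>%
    arrange(desc(.data$probability), .data$gene) %>%
    select("gene", "probability")
  cand$already_target_for <- map_chr(cand$gene, function(g) {
    if (is.null(target_diseases)) return(NA_character_)
    paste(names(target_diseases)[map_lgl(target_diseases, ~ g %in% .x)],
          collapse = ";")
  })
  cand
}
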