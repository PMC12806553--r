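#' Run the full classification pipeline
#'
#' Convenience wrapper chaining the stages: normalize counts, score
#' pathways, select discriminative pathways by rank-sum test on the
#' training cells, train the classifier on the training split, and
#' evaluate on the held-out split.
#'
#' @param counts Gene-by-cell raw count matrix.
#' @param gene_sets Named list of gene sets.
#' @param labels Cell labels.
#' @param split List with `train`/`test` cell indices (e.g. from
#'   [split_data()]); if `NULL`, a stratified 8:2 split is drawn with
#'   `seed`.
#' @param config [training_config()] for the network.
#' @param target_sum,log_transform Normalization parameters.
#' @param min_genes Minimum matched genes per pathway.
#' @param alpha Rank-sum retention threshold.
#' @param seed Seed for the split when `split` is `NULL`.
#' @return A list with `scores` (all cells), `selection` (the
#'   [wilcoxon_filter()] table), `model`, `split`, `predictions` (test
#'   cells) and `metrics` (test-set [evaluate_predictions()] report).
#' @export
run_pipeline <- function(counts, gene_sets, labels, split = NULL,
                         config = training_config(),
                         target_sum = 1e4, log_transform = TRUE,
                         min_genes = 3L, alpha = 0.05, seed = 1L) {
  y <- align_labels(labels, colnames(counts))
  if (is.null(split)) split <- split_data(y, config$split_ratio, seed)
  norm <- normalize_counts(counts, target_sum, log_transform)
  sc <- score_pathways(norm, gene_sets, min_genes = min_genes)
  train_m <- sc$scores[, split$train, drop = FALSE]
  selection <- wilcoxon_filter(train_m, y[split$train], alpha = alpha)
  kept <- selection$pathway[selection$retained]
  if (length(kept) == 0) input_abort("no pathway passed the rank-sum filter")
  model <- train_model(
    train_m[kept, , drop = FALSE], y[split$train], config = config,
    normalization = list(target_sum = target_sum, log_transform = log_transform)
  )
  preds <- predict(model, sc$scores[kept, split$test, drop = FALSE])
  metrics <- evaluate_predictions(preds, y[split$test])
  list(scores = sc, selection = selection, model = model, split = split,
       predictions = preds, metrics = metrics)
}
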