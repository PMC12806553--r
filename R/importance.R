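#' Permutation-based pathway importance
#'
#' Quantifies each pathway's contribution to the classifier: the
#' evaluation-set binary cross-entropy is computed once as baseline, then
#' each pathway's standardized score row is shuffled across cells (a
#' fresh permutation per repeat) and the loss recomputed; the mean loss
#' increase over repeats is that pathway's importance. Shuffling happens
#' on the standardized scale so the scaler is not refit per permutation —
#' the standard permutation-importance contract, isolating how the model
#' uses the feature. Permutations are seeded per (pathway, repeat), so
#' the table is reproducible regardless of evaluation order.
#'
#' @param model A `pathcell_model`.
#' @param scores Evaluation score matrix covering the model pathways.
#' @param labels Evaluation labels.
#' @param n_repeats Number of shuffles per pathway (default 100).
#' @param seed Base seed for the permutations.
#' @return An `importance_table` tibble: `pathway`, `mean_delta_loss`,
#'   `sd_delta_loss`, `rank` (1 = most important; ties broken by pathway
#'   name), `n_repeats`.
#' @export
permutation_importance <- function(model, scores, labels,
                                   n_repeats = 100L, seed = 1L) {
  if (n_repeats < 1) input_abort("n_repeats must be >= 1")
  z <- model_standardize(model, scores)
  y <- align_labels(labels, colnames(z))
  n <- ncol(z)
  base_loss <- bce_loss(mlp_forward(model$params, t(z))$out, y)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  p_names <- model$pathway_names
  delta <- matrix(NA_real_, length(p_names), n_repeats)
  for (pi in seq_along(p_names)) {
    zp <- z
    for (r in seq_len(n_repeats)) {
      set.seed(derive_seed(seed, pi, r))
      zp[pi, ] <- z[pi, sample.int(n)]
      loss <- bce_loss(mlp_forward(model$params, t(zp))$out, y)
      delta[pi, r] <- loss - base_loss
    }
  }
  mean_delta <- rowMeans(delta)
  sd_delta <- if (n_repeats > 1) apply(delta, 1, stats::sd) else rep(0, nrow(delta))
  ord <- order(-mean_delta, p_names)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  structure(
    tibble::tibble(
      pathway = p_names,
      mean_delta_loss = mean_delta,
      sd_delta_loss = sd_delta,
      rank = rank,
      n_repeats = as.integer(n_repeats)
    ),
    class = c("importance_table", "tbl_df", "tbl", "data.frame"),
    baseline_loss = base_loss
  )
}

#' Write an importance table as TSV
#'
#' @param importance An `importance_table`.
#' @param path Output file.
#' @export
write_importance <- function(importance, path) {
  utils::write.table(importance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
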