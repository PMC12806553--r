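#' Randomly retain a fixed number of detected genes per cell
#'
#' Degradation operator for the gene-retention robustness protocol: in
#' each cell, a uniform random subset of `min(n_retain, n_detected)` of
#' its detected (nonzero) genes keeps its counts and every other gene is
#' zeroed. Matrix dimensions and cell order are unchanged, emulating
#' cells sequenced to very different detected-gene depths.
#'
#' @param counts Gene-by-cell count matrix.
#' @param n_retain Number of detected genes to keep per cell (>= 1).
#' @param seed RNG seed.
#' @return A degraded count matrix of identical shape.
#' @export
retain_genes <- function(counts, n_retain, seed = 1L) {
  if (n_retain < 1) input_abort("n_retain must be >= 1")
  counts <- count_matrix(counts)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  t <- as(counts, "TsparseMatrix")
  keep <- logical(length(t@x))
  for (j in seq_len(ncol(counts))) {
    set.seed(derive_seed(seed, 7L, j))
    in_cell <- which(t@j == j - 1L)
    if (length(in_cell) <= n_retain) {
      keep[in_cell] <- TRUE
    } else {
      keep[in_cell[sample.int(length(in_cell), n_retain)]] <- TRUE
    }
  }
  out <- Matrix::sparseMatrix(
    i = t@i[keep] + 1L, j = t@j[keep] + 1L, x = t@x[keep],
    dims = dim(counts), dimnames = dimnames(counts)
  )
  as(as(out, "CsparseMatrix"), "generalMatrix")
}

#' Randomly inactivate a fraction of pathways
#'
#' Degradation operator for the pathway-inactivation protocol: a uniform
#' random subset of `floor(fraction * P)` pathways has its standardized
#' score rows set to 0 — the training mean — for all cells, removing that
#' feature's information from the classifier input. (Shuffling would
#' preserve marginal signal; zeroing is what "inactivation" implies.)
#'
#' @param standardized_scores Pathway-by-cell matrix on the standardized
#'   scale (see [apply_scaler()] or `predict(..., standardized = TRUE)`).
#' @param fraction Fraction of pathways to inactivate, in `[0, 1]`.
#' @param seed RNG seed.
#' @return A list with `scores` (modified matrix) and `inactivated`
#'   (pathway names zeroed).
#' @export
inactivate_pathways <- function(standardized_scores, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    input_abort("fraction must be in [0, 1]")
  }
  m <- as_score_matrix(standardized_scores)
  n_off <- floor(fraction * nrow(m) + 1e-9)  # guard float error in f*P
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 13L))
  off <- sort(sample.int(nrow(m), n_off))
  m[off, ] <- 0
  list(scores = m, inactivated = rownames(m)[off])
}

#' F1-versus-degradation robustness curve
#'
#' Runs one of the two degradation protocols over a grid of levels with
#' replicates and reports per-level classification metrics:
#' `gene_retention` degrades the raw counts (then re-scores and
#' re-standardizes through the full pipeline), `pathway_inactivation`
#' zeroes standardized score rows at predict time.
#'
#' @param model A `pathcell_model`.
#' @param labels Evaluation labels.
#' @param protocol `"gene_retention"` or `"pathway_inactivation"`.
#' @param levels Degradation levels: detected-gene counts for retention
#'   (default 100, 200, 500, 1000, 2000, 5000), inactivated fractions for
#'   inactivation (default 0, 0.2, 0.4, 0.6, 0.8).
#' @param counts Raw counts (required for `gene_retention`).
#' @param gene_sets Gene sets used to score (required for
#'   `gene_retention`).
#' @param scores Evaluation score matrix (required for
#'   `pathway_inactivation`; raw scale unless `standardized = TRUE`).
#' @param standardized Whether `scores` is already standardized.
#' @param n_replicates Replicate degradation draws per level (default 10).
#' @param seed Base seed.
#' @param min_genes Minimum matched genes when re-scoring.
#' @return A `robustness_curve` tibble: one row per (level, replicate)
#'   with `protocol`, `level`, `replicate`, `f1`, `accuracy`,
#'   `precision`, `recall`.
#' @export
robustness_curve <- function(model, labels,
                             protocol = c("gene_retention",
                                          "pathway_inactivation"),
                             levels = NULL,
                             counts = NULL, gene_sets = NULL,
                             scores = NULL, standardized = FALSE,
                             n_replicates = 10L, seed = 1L,
                             min_genes = 3L) {
  protocol <- match.arg(protocol)
  if (n_replicates < 1) input_abort("n_replicates must be >= 1")
  if (is.null(levels)) {
    levels <- if (protocol == "gene_retention") {
      c(100, 200, 500, 1000, 2000, 5000)
    } else {
      c(0, 0.2, 0.4, 0.6, 0.8)
    }
  }
  if (is.unsorted(levels, strictly = TRUE)) {
    input_abort("levels must be strictly increasing")
  }
  if (protocol == "gene_retention") {
    if (is.null(counts) || is.null(gene_sets)) {
      input_abort("gene_retention needs counts and gene_sets")
    }
    y_bc <- colnames(counts)
  } else {
    if (is.null(scores)) input_abort("pathway_inactivation needs scores")
    z0 <- if (standardized) {
      as_score_matrix(scores)[model$pathway_names, , drop = FALSE]
    } else {
      model_standardize(model, scores)
    }
    y_bc <- colnames(z0)
  }
  y <- align_labels(labels, y_bc)

  grid <- tidyr::expand_grid(level = levels,
                             replicate = seq_len(n_replicates))
  rows <- purrr::pmap(grid, function(level, replicate) {
    rep_seed <- derive_seed(seed, match(level, levels), replicate)
    preds <- if (protocol == "gene_retention") {
      degraded <- retain_genes(counts, level, seed = rep_seed)
      norm <- normalize_counts(degraded,
                               target_sum = model$normalization$target_sum,
                               log_transform = model$normalization$log_transform)
      sc <- score_pathways(norm, gene_sets, min_genes = min_genes)
      predict(model, sc)
    } else {
      z <- inactivate_pathways(z0, level, seed = rep_seed)$scores
      predict(model, z, standardized = TRUE)
    }
    met <- evaluate_predictions(preds, y)
    dplyr::select(met, dplyr::all_of(c("f1", "accuracy", "precision", "recall")))
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(rows))
  out$protocol <- protocol
  out <- dplyr::relocate(out, "protocol")
  structure(out,
            class = c("robustness_curve", "tbl_df", "tbl", "data.frame"),
            seed = seed, n_replicates = as.integer(n_replicates))
}

#' Summarize a robustness curve per level
#'
#' @param x A `robustness_curve`.
#' @param ... Unused.
#' @return A tibble with per-level mean and SD of F1 and accuracy.
#' @export
tidy.robustness_curve <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$protocol, .data$level),
    f1_mean = mean(.data$f1), f1_sd = stats::sd(.data$f1),
    accuracy_mean = mean(.data$accuracy),
    accuracy_sd = stats::sd(.data$accuracy),
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
}

#' Contrast models trained on top-k versus all-but-top-k pathways
#'
#' Trains two classifiers on the same training cells: one restricted to
#' the `k` most important pathways (per a permutation importance table),
#' one on every pathway except those, and evaluates both on the same test
#' cells. A large F1 gap confirms the top pathways carry the
#' discriminative signal.
#'
#' @param train_scores,train_labels Training score matrix and labels.
#' @param test_scores,test_labels Evaluation score matrix and labels.
#' @param importance An `importance_table` (or tibble with `pathway` and
#'   `rank`).
#' @param k Number of top pathways (default 4; must satisfy
#'   `1 <= k < P`).
#' @param config [training_config()] for both fits.
#' @return A list with `top_k` and `without_top_k`, each holding `model`,
#'   `metrics` and `pathways`.
#' @export
top_pathway_ablation <- function(train_scores, train_labels,
                                 test_scores, test_labels,
                                 importance, k = 4L,
                                 config = training_config()) {
  tr <- as_score_matrix(train_scores)
  te <- as_score_matrix(test_scores)
  if (k < 1) input_abort("k must be >= 1")
  if (k >= nrow(tr)) input_abort("k must be smaller than the number of pathways")
  top <- importance$pathway[order(importance$rank)][seq_len(k)]
  rest <- setdiff(rownames(tr), top)
  fit_eval <- function(pw) {
    mod <- train_model(tr[pw, , drop = FALSE], train_labels, config = config)
    preds <- predict(mod, te[pw, , drop = FALSE])
    list(model = mod,
         metrics = evaluate_predictions(preds, test_labels),
         pathways = pw)
  }
  list(top_k = fit_eval(top), without_top_k = fit_eval(rest))
}
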