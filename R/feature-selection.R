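#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The two-group test used to select discriminative pathways. For group
#' sizes of at most 8 the p-value is exact: from the null distribution of
#' the Mann-Whitney U statistic when there are no ties, and by complete
#' enumeration of all group assignments (with midranks) when there are.
#' Larger groups use the normal approximation with tie and continuity
#' corrections. Constant pooled data yields p = 1 by convention.
#'
#' @param x,y Numeric vectors for the two groups (x is the tumor group by
#'   convention downstream).
#' @param exact_max Largest group size for which the exact null
#'   distribution is used (default 8).
#' @return A list with `statistic` (the Mann-Whitney U of `x`) and
#'   `p_value` (two-sided).
#' @export
rank_sum_test <- function(x, y, exact_max = 8L) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) input_abort("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (n1 <= exact_max && n2 <= exact_max) {
    if (!ties) {
      p_lo <- stats::pwilcox(u, n1, n2)
      p_hi <- 1 - stats::pwilcox(u - 1, n1, n2)
      p <- min(1, 2 * min(p_lo, p_hi))
    } else {
      p <- enumerate_rank_sum_p(r, n1, u)
    }
  } else {
    p <- approx_rank_sum_p(r, n1, n2, u)
  }
  list(statistic = u, p_value = p)
}

# Exact two-sided p by enumerating all C(n1+n2, n1) assignments of the
# pooled (mid)ranks to group 1.
enumerate_rank_sum_p <- function(ranks, n1, u_obs) {
  n <- length(ranks)
  combos <- utils::combn(n, n1)
  offset <- n1 * (n1 + 1) / 2
  us <- colSums(matrix(ranks[combos], nrow = n1)) - offset
  eps <- 1e-8
  p_lo <- mean(us <= u_obs + eps)
  p_hi <- mean(us >= u_obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

# Normal approximation with tie correction and continuity correction.
approx_rank_sum_p <- function(ranks, n1, n2, u) {
  n <- n1 + n2
  tie_tab <- table(ranks)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  mu <- n1 * n2 / 2
  d <- max(0, abs(u - mu) - 0.5)  # continuity correction toward the mean
  min(1, 2 * stats::pnorm(-d / sqrt(sigma2)))
}

#' Select pathways separating tumor from normal cells
#'
#' Per pathway, a two-sided rank-sum test of tumor versus normal score
#' distributions; pathways with p below `alpha` are retained as
#' classifier features. No multiplicity correction is applied at this
#' training-time filtering step (the reporting-oriented
#' [differential_pathways()] does correct).
#'
#' @param scores A `pathway_scores` object or pathway-by-cell matrix.
#' @param labels Cell labels (tumor/normal strings, 0/1, or a tibble with
#'   `barcode` and `label`, matched to the score columns by barcode).
#' @param alpha Retention threshold on the raw p-value (default 0.05).
#' @return A tibble in input pathway order with columns `pathway`,
#'   `statistic`, `p_value`, `retained`.
#' @export
wilcoxon_filter <- function(scores, labels, alpha = 0.05) {
  m <- as_score_matrix(scores)
  y <- align_labels(labels, colnames(m))
  check_two_classes(y)
  res <- apply_rank_sum(m, y)
  dplyr::mutate(res, retained = .data$p_value < alpha)
}

apply_rank_sum <- function(m, y) {
  tests <- purrr::map(seq_len(nrow(m)), function(i) {
    row <- m[i, ]
    if (max(row) == min(row)) {
      list(statistic = sum(y == 1) * sum(y == 0) / 2, p_value = 1)
    } else {
      rank_sum_test(row[y == 1], row[y == 0])
    }
  })
  tibble::tibble(
    pathway = rownames(m),
    statistic = purrr::map_dbl(tests, "statistic"),
    p_value = purrr::map_dbl(tests, "p_value")
  )
}

# Align a label input to the score matrix columns; tibbles with barcodes
# are joined by barcode, bare vectors are taken positionally.
align_labels <- function(labels, barcodes) {
  if (is.data.frame(labels) && "barcode" %in% names(labels)) {
    idx <- match(barcodes, labels$barcode)
    if (anyNA(idx)) {
      input_abort(paste0(
        "cells missing from label table: ",
        paste(utils::head(barcodes[is.na(idx)], 5), collapse = ", ")
      ))
    }
    return(as_label01(labels$label[idx]))
  }
  y <- as_label01(labels)
  if (length(y) != length(barcodes)) {
    input_abort(sprintf("labels length (%d) != number of cells (%d)",
                        length(y), length(barcodes)))
  }
  y
}

#' Differential pathway analysis between tumor and normal cells
#'
#' Rank-sum p-values with Benjamini-Hochberg correction and a log2 fold
#' change of mean scores (tumor over normal, with a pseudocount guarding
#' zero means). A pathway is flagged when `|log2fc| > lfc_threshold` and
#' `fdr < fdr_threshold`, the reporting rule used for the up/down pathway
#' table.
#'
#' @inheritParams wilcoxon_filter
#' @param lfc_threshold Absolute log2 fold-change cut (default 1).
#' @param fdr_threshold BH-adjusted p cut (default 0.05).
#' @param epsilon Pseudocount added to both group means (default 0.01).
#' @return A tibble with `pathway`, `statistic`, `p_value`, `log2fc`,
#'   `fdr`, `flagged`.
#' @export
differential_pathways <- function(scores, labels, lfc_threshold = 1,
                                  fdr_threshold = 0.05, epsilon = 0.01) {
  m <- as_score_matrix(scores)
  y <- align_labels(labels, colnames(m))
  check_two_classes(y)
  res <- apply_rank_sum(m, y)
  mean_t <- unname(rowMeans(m[, y == 1, drop = FALSE]))
  mean_n <- unname(rowMeans(m[, y == 0, drop = FALSE]))
  res |>
    dplyr::mutate(
      log2fc = log2((mean_t + epsilon) / (mean_n + epsilon)),
      fdr = benjamini_hochberg(.data$p_value),
      flagged = abs(.data$log2fc) > lfc_threshold & .data$fdr < fdr_threshold
    )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, elementwise at least as large as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    input_abort("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
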