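#' Library-size normalize a count matrix
#'
#' Scales each cell so its total equals `target_sum`, then applies
#' `log1p`. Zeros stay zero, so sparsity is preserved. This is the
#' featurization pre-step before pathway scoring; the parameters are
#' recorded in trained models so scoring is reproducible at predict time.
#'
#' @param counts Gene-by-cell count matrix.
#' @param target_sum Library-size target each cell is scaled to
#'   (default 1e4, the de facto single-cell convention).
#' @param log_transform Apply `log1p` after scaling (default `TRUE`).
#' @return A sparse gene-by-cell matrix of normalized values.
#' @examples
#' m <- matrix(c(9, 0, 1, 1, 1, 0), 3, 2,
#'             dimnames = list(c("G1", "G2", "G3"), c("c1", "c2")))
#' normalize_counts(m, target_sum = 10)
#' @export
normalize_counts <- function(counts, target_sum = 1e4, log_transform = TRUE) {
  counts <- count_matrix(counts)
  if (!is.numeric(target_sum) || length(target_sum) != 1 || target_sum <= 0) {
    input_abort("target_sum must be a positive number")
  }
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    input_abort(paste0(
      "cells with zero total counts: ",
      paste(utils::head(colnames(counts)[totals == 0], 10), collapse = ", ")
    ))
  }
  out <- counts %*% Matrix::Diagonal(x = target_sum / totals)
  if (log_transform) out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  as(as(out, "CsparseMatrix"), "generalMatrix")
}

#' Score pathway activity per cell
#'
#' For each pathway the score in a cell is the mean normalized expression
#' over the pathway's genes that are present in the matrix, zeros
#' included. Averaging over dozens of genes pools signal across dropout
#' zeros, which is what lets the downstream classifier work on sparse
#' data; including zeros also keeps the detection-rate difference between
#' tumor and normal cells (tumor cells typically detect more genes) in
#' the features. Genes in a pathway but absent from the matrix are
#' ignored, and pathways matching fewer than `min_genes` genes are
#' dropped and reported.
#'
#' @param normalized Gene-by-cell matrix from [normalize_counts()].
#' @param gene_sets Named list of gene-symbol vectors (see [read_gmt()]).
#' @param min_genes Minimum matched genes for a pathway to be scored
#'   (default 3; a mean over fewer genes defeats the sparsity pooling).
#' @return An object of class `pathway_scores`: a list with `scores`
#'   (pathway-by-cell dense matrix), `n_genes_used` (named integer
#'   vector), and `dropped` (tibble of pathways excluded, with reasons).
#' @export
score_pathways <- function(normalized, gene_sets, min_genes = 3) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  if (anyDuplicated(names(gene_sets))) input_abort("duplicate pathway names")
  universe <- rownames(normalized)
  matched <- lapply(gene_sets, function(g) {
    intersect(canonical_symbols(g), universe)
  })
  n_matched <- vapply(matched, length, integer(1))
  if (all(n_matched == 0)) {
    input_abort(paste0(
      "no pathway gene matches the expression matrix; ",
      "gene-symbol namespace mismatch suspected"
    ))
  }
  keep <- n_matched >= min_genes
  dropped <- tibble::tibble(
    pathway = names(gene_sets)[!keep],
    n_matched = unname(n_matched[!keep]),
    reason = sprintf("matched %d genes < min_genes (%d)",
                     unname(n_matched[!keep]), min_genes)
  )
  if (!any(keep)) {
    input_abort("all pathways dropped by the min_genes filter")
  }
  kept <- matched[keep]
  # Pathway-by-gene averaging operator: row p has 1/|P| at p's genes.
  ii <- rep(seq_along(kept), lengths(kept))
  jj <- match(unlist(kept, use.names = FALSE), universe)
  op <- Matrix::sparseMatrix(
    i = ii, j = jj, x = 1 / lengths(kept)[ii],
    dims = c(length(kept), length(universe))
  )
  scores <- as.matrix(op %*% normalized)
  dimnames(scores) <- list(names(kept), colnames(normalized))
  structure(
    list(
      scores = scores,
      n_genes_used = stats::setNames(lengths(kept), names(kept)),
      dropped = dropped
    ),
    class = "pathway_scores"
  )
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat(sprintf(
    "<pathway_scores> %d pathways x %d cells (%d pathway(s) dropped)\n",
    nrow(x$scores), ncol(x$scores), nrow(x$dropped)
  ))
  invisible(x)
}

# Accept either a pathway_scores object or a bare pathway-by-cell matrix.
as_score_matrix <- function(scores) {
  if (inherits(scores, "pathway_scores")) return(scores$scores)
  if (is.matrix(scores) || inherits(scores, "Matrix")) {
    m <- as.matrix(scores)
    if (is.null(rownames(m))) input_abort("score matrix needs pathway rownames")
    return(m)
  }
  input_abort("expected a pathway_scores object or pathway-by-cell matrix")
}
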