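#' Validate and canonicalize a gene-by-cell count matrix
#'
#' Counts are stored as a sparse `dgCMatrix` (genes in rows, cells in
#' columns) with gene symbols as row names and cell barcodes as column
#' names. Gene symbols are uppercased and stripped of surrounding
#' whitespace so they match gene-set files reliably; duplicate symbols
#' that remain after canonicalization have their count rows summed into a
#' single row (standard aggregation, which keeps pathway membership
#' well-defined).
#'
#' @param counts A matrix or sparse Matrix of non-negative integer counts,
#'   genes in rows, cells in columns, with row and column names.
#' @return A validated `dgCMatrix` with canonical, unique gene symbols and
#'   unique barcodes.
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'             dimnames = list(c("tp53", "MYC"), c("c1", "c2")))
#' count_matrix(m)
#' @export
count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!inherits(counts, "Matrix") && !is.matrix(counts)) {
    input_abort("counts must be a matrix or sparse Matrix")
  }
  if (nrow(counts) < 1 || ncol(counts) < 1) {
    input_abort("count matrix needs at least 1 gene and 1 cell")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    input_abort("count matrix must carry gene symbols (rownames) and barcodes (colnames)")
  }
  m <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  vals <- m@x
  if (any(!is.finite(vals)) || any(vals < 0)) {
    format_abort("counts must be finite and non-negative")
  }
  if (any(vals != round(vals))) {
    format_abort("counts must be integral")
  }
  if (anyDuplicated(colnames(m))) {
    format_abort("duplicate cell barcodes in count matrix")
  }
  rownames(m) <- canonical_symbols(rownames(m))
  if (anyDuplicated(rownames(m))) {
    m <- sum_duplicate_genes(m)
  }
  m
}

# Sum count rows that share a canonical gene symbol; first occurrence order
# is preserved.
sum_duplicate_genes <- function(m) {
  sym <- rownames(m)
  keep <- unique(sym)
  idx <- match(sym, keep)
  agg <- Matrix::sparseMatrix(
    i = idx, j = seq_along(sym),
    x = 1, dims = c(length(keep), length(sym))
  )
  out <- agg %*% m
  out <- as(as(out, "CsparseMatrix"), "generalMatrix")
  dimnames(out) <- list(keep, colnames(m))
  out
}

#' Per-cell detected-gene counts
#'
#' Number of genes with nonzero counts in each cell; tumor cells typically
#' detect more genes than normal cells, a signal the pathway scores
#' deliberately preserve.
#'
#' @param counts A gene-by-cell count matrix.
#' @return A tibble with columns `barcode` and `n_detected`.
#' @export
detected_genes <- function(counts) {
  counts <- count_matrix(counts)
  tibble::tibble(
    barcode = colnames(counts),
    n_detected = Matrix::colSums(counts > 0)
  )
}
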