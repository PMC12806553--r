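#' Read a 10x-style MatrixMarket count directory
#'
#' Expects `matrix.mtx` (optionally gzipped), a gene/feature TSV
#' (`features.tsv` or `genes.tsv`), and `barcodes.tsv` in one directory,
#' the layout written by Cell Ranger. MatrixMarket 1-based triplet indices
#' are converted to the internal convention on read. Gene symbols are
#' taken from the second column of the feature file when present
#' (Cell Ranger writes id, symbol, type), otherwise the first.
#'
#' @param path Directory containing the three files.
#' @return A gene-by-cell sparse count matrix (see [count_matrix()]);
#'   duplicate gene symbols are summed.
#' @export
read_10x_counts <- function(path) {
  if (!dir.exists(path)) format_abort(paste0("not a directory: ", path))
  mtx <- find_10x_file(path, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- find_10x_file(path, c(
    "features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"
  ))
  bc <- find_10x_file(path, c("barcodes.tsv", "barcodes.tsv.gz"))

  m <- Matrix::readMM(mtx)
  if (any(m@x != round(m@x))) {
    format_abort(paste0("non-integer values in ", mtx))
  }
  features <- utils::read.delim(feat, header = FALSE, colClasses = "character")
  barcodes <- utils::read.delim(bc, header = FALSE, colClasses = "character")
  if (nrow(features) != nrow(m)) {
    format_abort(sprintf(
      "dimension mismatch: matrix has %d rows but %s has %d lines",
      nrow(m), basename(feat), nrow(features)
    ))
  }
  if (nrow(barcodes) != ncol(m)) {
    format_abort(sprintf(
      "dimension mismatch: matrix has %d columns but %s has %d lines",
      ncol(m), basename(bc), nrow(barcodes)
    ))
  }
  symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  dimnames(m) <- list(symbols, barcodes[[1]])
  count_matrix(m)
}

find_10x_file <- function(path, candidates) {
  for (f in candidates) {
    full <- file.path(path, f)
    if (file.exists(full)) return(full)
  }
  format_abort(paste0(
    "missing file in ", path, ": expected one of ",
    paste(candidates, collapse = ", ")
  ))
}

#' Write a count matrix as a 10x-style MatrixMarket directory
#'
#' Emits `matrix.mtx`, `features.tsv` and `barcodes.tsv` so generated data
#' can be round-tripped through [read_10x_counts()].
#'
#' @param counts Gene-by-cell count matrix.
#' @param path Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_10x_counts <- function(counts, path) {
  counts <- count_matrix(counts)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  t <- as(counts, "TsparseMatrix")
  mtx <- file.path(path, "matrix.mtx")
  con <- file(mtx, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(counts), ncol(counts), length(t@x)), con)
  ord <- order(t@j, t@i)
  writeLines(sprintf("%d %d %d", t@i[ord] + 1L, t@j[ord] + 1L,
                     as.integer(t@x[ord])), con)
  utils::write.table(
    data.frame(id = rownames(counts), symbol = rownames(counts),
               type = "Gene Expression"),
    file.path(path, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Read a dense count table (CSV or TSV)
#'
#' @param path File path; `.csv` is comma-separated, anything else
#'   tab-separated. First column holds row names, first row column names.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`;
#'   the result is always genes-by-cells.
#' @return A gene-by-cell sparse count matrix.
#' @export
read_dense_counts <- function(path,
                              orientation = c("genes_by_cells", "cells_by_genes")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) format_abort(paste0("file not found: ", path))
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df, 2, as.numeric))), arr.ind = TRUE)
    loc <- if (length(bad) > 0) {
      sprintf(" (row %d, column %d)", bad[1, 1], bad[1, 2])
    } else ""
    format_abort(paste0("non-numeric entry in ", path, loc))
  }
  if (any(m < 0, na.rm = TRUE)) {
    bad <- which(m < 0, arr.ind = TRUE)
    format_abort(sprintf(
      "negative count at row '%s', column '%s' in %s",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path
    ))
  }
  if (orientation == "cells_by_genes") m <- t(m)
  count_matrix(m)
}

#' Write a count matrix as a dense TSV
#'
#' Integer counts, genes in rows; an exact-identity round trip with
#' [read_dense_counts()].
#'
#' @param counts Gene-by-cell count matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dense_counts <- function(counts, path) {
  counts <- count_matrix(counts)
  m <- as.matrix(counts)
  storage.mode(m) <- "integer"
  utils::write.table(
    data.frame(gene = rownames(m), m, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' One gene set per line: name, description, then gene symbols, all
#' tab-separated. Symbols are uppercase-canonicalized; duplicates within a
#' line are collapsed.
#'
#' @param path GMT file path.
#' @return A named list of character vectors of gene symbols, with
#'   attribute `source` recording the file it came from.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) format_abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) format_abort(paste0("empty GMT file: ", path))
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      format_abort(sprintf("GMT line %d has %d fields; need >= 3 (name, description, genes...)",
                           i, length(fields)))
    }
    nms[i] <- fields[1]
    genes <- unique(canonical_symbols(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      format_abort(sprintf("GMT line %d ('%s') has no genes", i, fields[1]))
    }
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) {
    format_abort(paste0(
      "duplicate pathway name(s) in GMT: ",
      paste(unique(nms[duplicated(nms)]), collapse = ", ")
    ))
  }
  names(sets) <- nms
  attr(sets, "source") <- path
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param gene_sets Named list of gene symbol vectors.
#' @param path Output file.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a per-cell label table
#'
#' A two-column TSV (`barcode`, `label`) with labels `tumor` or `normal`.
#'
#' @param path File path.
#' @return For `read_labels`, a tibble with columns `barcode` and `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) format_abort(paste0("file not found: ", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "label") %in% names(df))) {
    format_abort("label TSV must have columns 'barcode' and 'label'")
  }
  as_label01(df$label)  # validates values
  tibble::as_tibble(df[, c("barcode", "label")])
}

#' @rdname read_labels
#' @param labels Tibble with `barcode` and `label`, or a vector accepted by
#'   the package's label coercion plus `barcodes`.
#' @param barcodes Barcodes when `labels` is a bare vector.
#' @export
write_labels <- function(labels, path, barcodes = NULL) {
  if (!is.data.frame(labels)) {
    stopifnot(!is.null(barcodes))
    labels <- tibble::tibble(barcode = barcodes,
                             label = label_names(as_label01(labels)))
  }
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a pathway-by-cell score matrix as TSV
#'
#' Full-precision text serialization of the dense activity-score matrix.
#'
#' @param scores Pathway-by-cell numeric matrix.
#' @param path File path.
#' @return For `read_score_matrix`, the score matrix.
#' @export
write_score_matrix <- function(scores, path) {
  df <- data.frame(pathway = rownames(scores),
                   apply(scores, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE)
  colnames(df) <- c("pathway", colnames(scores))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) format_abort(paste0("file not found: ", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
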