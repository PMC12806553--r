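# Shared fixtures, all built in code at test time.

tiny_counts <- function() {
  m <- matrix(
    c(1L, 0L, 2L,
      0L, 3L, 0L,
      4L, 0L, 5L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("TP53", "MYC", "EGFR"), c("cellA", "cellB", "cellC"))
  )
  count_matrix(m)
}

# Writes a hand-rolled 3 genes x 2 cells MatrixMarket fixture and returns
# the directory. `n_feature_lines` lets tests force a dimension mismatch.
write_tiny_10x <- function(dir, n_feature_lines = 3, gene_names = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(
    "%%MatrixMarket matrix coordinate integer general",
    "3 2 4",
    "1 1 5",
    "3 1 2",
    "2 2 7",
    "3 2 1"
  ), file.path(dir, "matrix.mtx"))
  if (is.null(gene_names)) gene_names <- c("TP53", "MYC", "EGFR")
  feats <- data.frame(
    id = paste0("ENSG", seq_len(n_feature_lines)),
    symbol = rep_len(gene_names, n_feature_lines),
    type = "Gene Expression"
  )
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(c("AAAC", "GGGT"), file.path(dir, "barcodes.tsv"))
  dir
}

# A small synthetic dataset with a trained pipeline, computed once per
# test run and cached.
.fixtures <- new.env(parent = emptyenv())

small_pipeline <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- simulation_config(
      n_tumor = 150L, n_normal = 150L, n_genes = 1000L, n_pathways = 20L,
      genes_per_pathway = c(15L, 25L), n_up_pathways = 3L,
      n_down_pathways = 3L, effect_log2fc = 1, tumor_library_scale = 1.5,
      seed = 42L
    )
    ds <- generate_dataset(cfg)
    res <- run_pipeline(ds$counts, ds$gene_sets, ds$labels,
                        config = training_config(max_epochs = 60, seed = 7),
                        seed = 7)
    .fixtures$small <- list(ds = ds, res = res)
  }
  .fixtures$small
}

# The frozen acceptance dataset + fitted pipeline, cached for the
# acceptance test file.
acceptance_pipeline <- function(seed = 1L) {
  key <- paste0("acc", seed)
  if (is.null(.fixtures[[key]])) {
    ds <- make_acceptance_dataset(seed = seed)
    res <- run_pipeline(ds$counts, ds$gene_sets, ds$labels,
                        split = ds$split, seed = seed)
    .fixtures[[key]] <- list(ds = ds, res = res)
  }
  .fixtures[[key]]
}

# Brute-force two-sided rank-sum p-value by enumerating every assignment
# of the pooled observations to the first group. Written independently of
# the implementation (counts extreme rank sums directly).
brute_force_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  sums <- apply(utils::combn(length(pooled), n1), 2,
                function(idx) sum(r[idx]))
  lo <- mean(sums <= obs + 1e-8)
  hi <- mean(sums >= obs - 1e-8)
  min(1, 2 * min(lo, hi))
}
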