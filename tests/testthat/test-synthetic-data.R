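test_that("configs validate their invariants", {
  expect_error(simulation_config(n_up_pathways = 60, n_down_pathways = 60,
                                 n_pathways = 100),
               class = "pathcell_input_error")
  expect_error(simulation_config(n_genes = 100, n_pathways = 50,
                                 genes_per_pathway = c(10, 12)),
               class = "pathcell_input_error")
  expect_error(simulation_config(dispersion = 0))
})

test_that("generation is deterministic and matches the configured shape", {
  cfg <- simulation_config(n_tumor = 30L, n_normal = 20L, n_genes = 300L,
                           n_pathways = 8L, genes_per_pathway = c(10L, 15L),
                           n_up_pathways = 2L, n_down_pathways = 1L, seed = 9L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(as.matrix(d1$counts), as.matrix(d2$counts))
  expect_identical(d1$gene_sets, d2$gene_sets)
  expect_identical(d1$truth$up_pathways, d2$truth$up_pathways)

  expect_equal(dim(d1$counts), c(300, 50))
  expect_equal(d1$labels$label, rep(c("tumor", "normal"), c(30, 20)))
  expect_length(d1$truth$up_pathways, 2)
  expect_length(d1$truth$down_pathways, 1)
  expect_length(intersect(d1$truth$up_pathways, d1$truth$down_pathways), 0)
  # pathways are non-overlapping partitions of a gene subset
  all_genes <- unlist(d1$gene_sets)
  expect_equal(anyDuplicated(all_genes), 0)
  # planted sets consistent with the emitted collection
  expect_true(all(d1$truth$up_pathways %in% names(d1$gene_sets)))
})

test_that("counts match the negative-binomial dropout moments", {
  cfg <- simulation_config(n_tumor = 1000L, n_normal = 1000L, n_genes = 200L,
                           n_pathways = 5L, genes_per_pathway = c(10L, 15L),
                           n_up_pathways = 0L, n_down_pathways = 0L,
                           effect_log2fc = 0, tumor_library_scale = 1,
                           seed = 14L)
  ds <- generate_dataset(cfg)
  mu <- ds$truth$gene_means$mean_normal
  p_drop <- plogis(-cfg$dropout_slope * (log(mu) - cfg$dropout_midpoint))
  expected <- mu * (1 - p_drop)
  observed <- Matrix::rowMeans(ds$counts)
  # moment check: tight agreement for well-expressed genes at n = 2000
  hi <- mu > 0.5
  expect_gt(sum(hi), 20)
  expect_lt(median(abs(observed[hi] - expected[hi]) / expected[hi]), 0.1)
  expect_gt(cor(observed, expected), 0.98)
})

test_that("tumor cells detect more genes when the library scale is raised", {
  cfg <- simulation_config(n_tumor = 300L, n_normal = 300L, n_genes = 800L,
                           n_pathways = 10L, genes_per_pathway = c(15L, 25L),
                           n_up_pathways = 0L, n_down_pathways = 0L,
                           effect_log2fc = 0, tumor_library_scale = 2,
                           seed = 18L)
  ds <- generate_dataset(cfg)
  det <- detected_genes(ds$counts)
  y <- ds$labels$label
  p <- wilcox.test(det$n_detected[y == "tumor"], det$n_detected[y == "normal"],
                   alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("the zero fraction rises with the dropout midpoint", {
  base <- list(n_tumor = 100L, n_normal = 100L, n_genes = 300L,
               n_pathways = 5L, genes_per_pathway = c(10L, 15L),
               n_up_pathways = 0L, n_down_pathways = 0L, effect_log2fc = 0,
               tumor_library_scale = 1, seed = 25L)
  zero_frac <- vapply(c(-2, 0, 2), function(mid) {
    cfg <- do.call(simulation_config, c(base, list(dropout_midpoint = mid)))
    counts <- generate_dataset(cfg)$counts
    1 - length(counts@x) / prod(dim(counts))
  }, numeric(1))
  expect_true(all(diff(zero_frac) > 0))
})

test_that("zero planted effect makes the classes exchangeable end to end", {
  cfg <- simulation_config(n_tumor = 120L, n_normal = 120L, n_genes = 800L,
                           n_pathways = 15L, genes_per_pathway = c(15L, 25L),
                           n_up_pathways = 0L, n_down_pathways = 0L,
                           effect_log2fc = 0, tumor_library_scale = 1,
                           seed = 30L)
  ds <- generate_dataset(cfg)
  res <- run_pipeline(ds$counts, ds$gene_sets, ds$labels,
                      config = training_config(max_epochs = 30, seed = 30),
                      alpha = 1, seed = 30)  # keep all pathways: nothing real to select
  expect_gt(res$metrics$accuracy, 0.25)
  expect_lt(res$metrics$accuracy, 0.75)
})

test_that("the acceptance bundle echoes its frozen configuration", {
  # small stand-in proportions are not used here: this is the real frozen
  # config, so only cheap shape checks run on it
  acc <- acceptance_pipeline(seed = 1L)
  expect_equal(dim(acc$ds$counts), c(5000, 2000))
  expect_equal(length(acc$ds$gene_sets), 100)
  expect_true(all(lengths(acc$ds$gene_sets) >= 25 &
                  lengths(acc$ds$gene_sets) <= 60))
  expect_length(acc$ds$truth$up_pathways, 10)
  expect_length(acc$ds$truth$down_pathways, 10)
  expect_length(acc$ds$split$train, 1600)

  # planted pathways are overwhelmingly detected by the rank-sum filter
  sel <- acc$res$selection
  planted <- c(acc$ds$truth$up_pathways, acc$ds$truth$down_pathways)
  expect_gte(sum(sel$retained[sel$pathway %in% planted]), 18)
})
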