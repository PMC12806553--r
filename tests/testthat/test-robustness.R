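test_that("gene retention keeps exactly min(n_retain, detected) genes per cell", {
  sp <- small_pipeline()
  counts <- sp$ds$counts[, 1:40]
  before <- Matrix::colSums(counts > 0)

  deg <- retain_genes(counts, 30, seed = 2)
  after <- Matrix::colSums(deg > 0)
  expect_equal(unname(after), unname(pmin(30, before)))
  expect_equal(dim(deg), dim(counts))
  expect_equal(dimnames(deg), dimnames(counts))
  # kept entries are unchanged
  expect_true(all(as.matrix(deg)[as.matrix(deg) > 0] ==
                  as.matrix(counts)[as.matrix(deg) > 0]))

  # retaining more genes than any cell detects is the identity
  expect_identical(as.matrix(retain_genes(counts, max(before) + 10, seed = 1)),
                   as.matrix(counts))

  one <- retain_genes(counts, 1, seed = 3)
  expect_true(all(Matrix::colSums(one > 0) <= 1))

  expect_error(retain_genes(counts, 0), class = "pathcell_input_error")
})

test_that("pathway inactivation zeroes the requested fraction of rows", {
  m <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(paste0("P", 1:10), paste0("c", 1:6)))
  expect_identical(inactivate_pathways(m, 0, seed = 1)$scores, m)

  res <- inactivate_pathways(m, 0.6, seed = 1)
  expect_length(res$inactivated, 6)
  expect_true(all(res$scores[res$inactivated, ] == 0))
  untouched <- setdiff(rownames(m), res$inactivated)
  expect_identical(res$scores[untouched, ], m[untouched, ])

  all_off <- inactivate_pathways(m, 1, seed = 1)
  expect_true(all(all_off$scores == 0))

  expect_error(inactivate_pathways(m, 1.2), class = "pathcell_input_error")
})

test_that("robustness curves hit their degenerate levels exactly", {
  sp <- small_pipeline()
  model <- sp$res$model
  test_idx <- sp$res$split$test
  y <- sp$ds$labels$label[test_idx]
  scores <- sp$res$scores$scores[model$pathway_names, test_idx, drop = FALSE]

  base_f1 <- evaluate_predictions(predict(model, scores), y)$f1

  # full gene retention reproduces the undegraded F1
  curve_g <- robustness_curve(
    model, y, protocol = "gene_retention",
    levels = c(nrow(sp$ds$counts)),
    counts = sp$ds$counts[, test_idx], gene_sets = sp$ds$gene_sets,
    n_replicates = 2, seed = 1
  )
  expect_equal(curve_g$f1, rep(base_f1, 2))

  # full inactivation equals the constant-input baseline
  z <- apply_scaler(scores, model$scaler)
  zero_preds <- predict(model, z * 0, standardized = TRUE)
  zero_f1 <- evaluate_predictions(zero_preds, y)$f1
  curve_p <- robustness_curve(
    model, y, protocol = "pathway_inactivation", levels = c(0, 1),
    scores = scores, n_replicates = 1, seed = 1
  )
  expect_equal(curve_p$f1[curve_p$level == 1], zero_f1)
  expect_equal(curve_p$f1[curve_p$level == 0], base_f1)

  s <- tidy(curve_p)
  expect_equal(nrow(s), 2)
  expect_error(robustness_curve(model, y, protocol = "pathway_inactivation",
                                levels = c(0.5, 0.2), scores = scores),
               class = "pathcell_input_error")
})

test_that("gene-retention F1 is non-decreasing in retained genes on synthetic data", {
  sp <- small_pipeline()
  model <- sp$res$model
  test_idx <- sp$res$split$test
  y <- sp$ds$labels$label[test_idx]
  curve <- robustness_curve(
    model, y, protocol = "gene_retention", levels = c(20, 100, 500),
    counts = sp$ds$counts[, test_idx], gene_sets = sp$ds$gene_sets,
    n_replicates = 3, seed = 5
  )
  s <- tidy(curve)
  # monotone within 2 SD of the replicate spread
  for (i in seq_len(nrow(s) - 1)) {
    slack <- 2 * max(s$f1_sd[i], s$f1_sd[i + 1], 0.02)
    expect_gte(s$f1_mean[i + 1], s$f1_mean[i] - slack)
  }
})

test_that("ablation validates k and reports complete confusion counts", {
  sp <- small_pipeline()
  kept <- sp$res$model$pathway_names
  tr <- sp$res$scores$scores[kept, sp$res$split$train, drop = FALSE]
  te <- sp$res$scores$scores[kept, sp$res$split$test, drop = FALSE]
  ytr <- sp$ds$labels$label[sp$res$split$train]
  yte <- sp$ds$labels$label[sp$res$split$test]
  imp <- tibble::tibble(pathway = kept, rank = seq_along(kept))

  expect_error(top_pathway_ablation(tr, ytr, te, yte, imp, k = length(kept)),
               class = "pathcell_input_error")
  expect_error(top_pathway_ablation(tr, ytr, te, yte, imp, k = 0),
               class = "pathcell_input_error")

  ab <- top_pathway_ablation(tr, ytr, te, yte, imp, k = 2,
                             config = training_config(max_epochs = 15, seed = 2))
  expect_equal(ab$top_k$pathways, kept[1:2])
  for (side in ab) {
    m <- side$metrics
    expect_equal(m$tp + m$fp + m$tn + m$fn, length(yte))
  }
})
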