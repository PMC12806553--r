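test_that("stratified splits preserve class balance and partition the cells", {
  y <- rep(c("tumor", "normal"), each = 100)
  sp <- split_data(y, split_ratio = 0.8, seed = 3)
  expect_length(sp$train, 160)
  expect_length(sp$test, 40)
  expect_equal(sum(y[sp$train] == "tumor"), 80)
  expect_equal(sum(y[sp$test] == "tumor"), 20)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))

  expect_identical(split_data(y, seed = 3), sp)
  expect_false(identical(split_data(y, seed = 4)$train, sp$train))

  expect_error(split_data(c("tumor", "normal", "normal")),
               class = "pathcell_input_error")
})

test_that("the scaler standardizes with population SD and handles constants", {
  m <- matrix(c(1, 2, 3,
                5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "CONST"), paste0("c", 1:3)))
  sc <- fit_scaler(m)
  expect_equal(unname(sc$means), c(2, 5))
  expect_equal(unname(sc$scales), c(sqrt(2 / 3), 1))
  z <- apply_scaler(m, sc)
  expect_equal(unname(z["A", ]), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-7)
  expect_equal(unname(z["CONST", ]), c(0, 0, 0))
  expect_equal(unname(rowMeans(z)), c(0, 0))
})

make_separable_scores <- function(n_per_class = 100, n_pathways = 5, delta = 2,
                                  seed = 31) {
  set.seed(seed)
  tumor <- matrix(rnorm(n_pathways * n_per_class, mean = delta),
                  n_pathways, n_per_class)
  normal <- matrix(rnorm(n_pathways * n_per_class, mean = -delta),
                   n_pathways, n_per_class)
  m <- cbind(tumor, normal)
  dimnames(m) <- list(paste0("P", seq_len(n_pathways)),
                      sprintf("c%03d", seq_len(2 * n_per_class)))
  list(scores = m, labels = rep(c(1, 0), each = n_per_class))
}

test_that("training separates a linearly separable toy problem", {
  toy <- make_separable_scores()
  sp <- split_data(toy$labels, seed = 1)
  model <- train_model(toy$scores[, sp$train], toy$labels[sp$train],
                       config = training_config(max_epochs = 60, seed = 1))
  preds <- predict(model, toy$scores[, sp$test])
  met <- evaluate_predictions(preds, toy$labels[sp$test])
  expect_equal(met$f1, 1)

  # independent oracle: logistic regression also separates it perfectly
  fit <- suppressWarnings(
    glm(y ~ ., data = data.frame(y = toy$labels[sp$train],
                                 t(toy$scores[, sp$train])),
        family = binomial())
  )
  oracle <- as.integer(predict(
    fit, newdata = data.frame(t(toy$scores[, sp$test])), type = "response"
  ) >= 0.5)
  expect_equal(mean(oracle == toy$labels[sp$test]), 1)
})

test_that("shuffled labels give chance-level held-out performance", {
  toy <- make_separable_scores(n_per_class = 80)
  accs <- vapply(1:3, function(s) {
    set.seed(1000 + s)
    y_shuf <- sample(toy$labels)
    sp <- split_data(y_shuf, seed = s)
    model <- train_model(toy$scores[, sp$train], y_shuf[sp$train],
                         config = training_config(max_epochs = 30, seed = s))
    evaluate_predictions(predict(model, toy$scores[, sp$test]),
                         y_shuf[sp$test])$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("training is bit-deterministic given a seed", {
  toy <- make_separable_scores(n_per_class = 40)
  cfg <- training_config(max_epochs = 15, seed = 9)
  m1 <- train_model(toy$scores, toy$labels, config = cfg)
  m2 <- train_model(toy$scores, toy$labels, config = cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, toy$scores), predict(m2, toy$scores))

  expect_error(train_model(toy$scores, rep(1, ncol(toy$scores))),
               class = "pathcell_input_error")
})

test_that("prediction aligns by pathway name and applies the threshold convention", {
  # hand-built model: identity passthrough of one pathway, zero weights,
  # so every probability is exactly sigmoid(0) = 0.5
  model <- structure(list(
    pathway_names = c("P1", "P2"),
    scaler = list(means = c(P1 = 0, P2 = 0), scales = c(P1 = 1, P2 = 1)),
    params = list(w = list(matrix(0, 2, 1)), b = list(0)),
    threshold = 0.5,
    config = training_config(),
    seed = 1L,
    normalization = list(target_sum = 1e4, log_transform = TRUE),
    training = list()
  ), class = "pathcell_model")
  m <- matrix(rnorm(6), 2, 3, dimnames = list(c("P1", "P2"), c("a", "b", "d")))
  preds <- predict(model, m)
  expect_equal(preds$probability, rep(0.5, 3))
  expect_equal(preds$call, rep("tumor", 3))  # >= threshold goes to tumor

  sp <- small_pipeline()
  model2 <- sp$res$model
  scores <- sp$res$scores$scores[model2$pathway_names, 1:8]
  base <- predict(model2, scores)
  shuffled <- scores[sample(nrow(scores)), , drop = FALSE]
  expect_identical(predict(model2, shuffled), base)

  expect_error(predict(model2, scores[-1, , drop = FALSE]),
               regexp = model2$pathway_names[1],
               class = "pathcell_input_error")
})

test_that("metrics match the confusion formulas and conventions", {
  calls <- rep(c(1, 1, 0, 0), c(8, 2, 2, 8))
  truth <- rep(c(1, 0, 1, 0), c(8, 2, 2, 8))
  met <- evaluate_predictions(calls, truth)
  expect_equal(met$precision, 0.8)
  expect_equal(met$recall, 0.8)
  expect_equal(met$f1, 0.8)
  expect_equal(met$accuracy, 0.8)
  expect_equal(c(met$tp, met$fp, met$tn, met$fn), c(8, 2, 8, 2))

  perfect <- evaluate_predictions(truth, truth)
  expect_equal(unlist(perfect[, c("f1", "accuracy", "precision", "recall")]),
               c(f1 = 1, accuracy = 1, precision = 1, recall = 1))

  degenerate <- evaluate_predictions(c(0, 0), c(0, 0))
  expect_equal(degenerate$f1, 0)
  expect_equal(degenerate$accuracy, 1)

  # brute-force confusion counting oracle on random vectors
  set.seed(44)
  for (i in 1:5) {
    yhat <- rbinom(30, 1, 0.4)
    y <- rbinom(30, 1, 0.6)
    met <- evaluate_predictions(yhat, y)
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (k in seq_along(y)) {
      if (yhat[k] == 1 && y[k] == 1) tp <- tp + 1
      if (yhat[k] == 1 && y[k] == 0) fp <- fp + 1
      if (yhat[k] == 0 && y[k] == 0) tn <- tn + 1
      if (yhat[k] == 0 && y[k] == 1) fn <- fn + 1
    }
    expect_equal(c(met$tp, met$fp, met$tn, met$fn), c(tp, fp, tn, fn))
    expect_equal(met$tp + met$fp + met$tn + met$fn, 30)
  }

  expect_error(evaluate_predictions(c(1, 0), c(1, 0, 1)),
               class = "pathcell_input_error")
})

test_that("imbalanced data metrics match hand-computed confusion arithmetic", {
  # 90/10 imbalance with a predictor that calls every cell normal except
  # half the true tumor cells
  truth <- rep(c(1, 0), c(10, 90))
  calls <- c(rep(1, 5), rep(0, 95))
  met <- evaluate_predictions(calls, truth)
  expect_equal(met$precision, 1)       # 5 / (5 + 0)
  expect_equal(met$recall, 0.5)        # 5 / (5 + 5)
  expect_equal(met$f1, 2 * 1 * 0.5 / 1.5)
  expect_equal(met$accuracy, 95 / 100)
})

test_that("tidy and glance expose the model structure", {
  sp <- small_pipeline()
  td <- tidy(sp$res$model)
  expect_equal(nrow(td), length(sp$res$model$pathway_names))
  expect_true(all(td$scaler_scale > 0))
  gl <- glance(sp$res$model)
  expect_equal(gl$n_pathways, nrow(td))
  expect_gt(gl$n_parameters, 0)
})
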