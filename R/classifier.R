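#' Training configuration for the cell classifier
#'
#' Hyperparameters of the fully connected network. The defaults — two
#' hidden ReLU layers of 128 and 64 units with dropout 0.3, Adam at 1e-3,
#' batches of 256, at most 200 epochs with early stopping at patience 10
#' — suit the small feature space (on the order of a hundred selected
#' pathways); all are recorded in the model artifact.
#'
#' @param hidden_sizes Integer vector of hidden layer widths.
#' @param dropout_rate Dropout probability applied after each hidden
#'   layer during training, in `[0, 1)`.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Epochs without internal-validation improvement before
#'   stopping.
#' @param val_fraction Fraction of the training cells held out internally
#'   for early stopping (default 0.1, stratified).
#' @param split_ratio Train fraction used by [split_data()] callers
#'   (default 0.8, the 8:2 convention).
#' @param seed RNG seed controlling initialization, shuffling and
#'   dropout; fixed seed plus fixed data gives bit-identical models.
#' @return A `training_config` list.
#' @export
training_config <- function(hidden_sizes = c(128L, 64L),
                            dropout_rate = 0.3,
                            learning_rate = 1e-3,
                            batch_size = 256L,
                            max_epochs = 200L,
                            patience = 10L,
                            val_fraction = 0.1,
                            split_ratio = 0.8,
                            seed = 1L) {
  stopifnot(
    length(hidden_sizes) >= 1, all(hidden_sizes >= 1),
    dropout_rate >= 0, dropout_rate < 1,
    learning_rate > 0, batch_size >= 1, max_epochs >= 1, patience >= 1,
    val_fraction > 0, val_fraction < 1,
    split_ratio > 0, split_ratio < 1
  )
  structure(
    list(
      hidden_sizes = as.integer(hidden_sizes),
      dropout_rate = dropout_rate,
      learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs),
      patience = as.integer(patience),
      val_fraction = val_fraction,
      split_ratio = split_ratio,
      seed = as.integer(seed)
    ),
    class = "training_config"
  )
}

#' Stratified train/test split
#'
#' Randomly divides cells into training and test sets at `split_ratio`
#' (default the 8:2 convention), stratified so class proportions are
#' preserved to within one cell. Deterministic given `seed`.
#'
#' @param labels Cell labels (any form accepted by the package).
#' @param split_ratio Fraction assigned to training.
#' @param seed RNG seed.
#' @return A list with integer index vectors `train` and `test`
#'   (disjoint, jointly exhaustive).
#' @export
split_data <- function(labels, split_ratio = 0.8, seed = 1L) {
  y <- as_label01(labels)
  check_two_classes(y)
  stopifnot(split_ratio > 0, split_ratio < 1)
  train <- integer(0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 101L))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    n_train <- round(split_ratio * length(idx))
    n_train <- max(1L, min(length(idx) - 1L, n_train))
    train <- c(train, sort(sample(idx, n_train)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Per-pathway standardization
#'
#' `fit_scaler` computes per-pathway means and population standard
#' deviations on the training score matrix; zero-variance pathways get
#' scale 1 so standardization never divides by zero. `apply_scaler`
#' standardizes any score matrix with a fitted scaler.
#'
#' @param scores Pathway-by-cell score matrix (or `pathway_scores`).
#' @return For `fit_scaler`, a list with `means` and `scales` (named by
#'   pathway); for `apply_scaler`, the standardized matrix.
#' @export
fit_scaler <- function(scores) {
  m <- as_score_matrix(scores)
  means <- rowMeans(m)
  scales <- sqrt(rowMeans((m - means)^2))
  scales[scales == 0] <- 1
  list(means = means, scales = scales)
}

#' @rdname fit_scaler
#' @param scaler A list from `fit_scaler`.
#' @export
apply_scaler <- function(scores, scaler) {
  m <- as_score_matrix(scores)
  if (!setequal(rownames(m), names(scaler$means)) &&
      length(scaler$means) != nrow(m)) {
    input_abort("scaler and score matrix have different pathways")
  }
  (m - scaler$means) / scaler$scales
}

# ---- network internals -----------------------------------------------------

mlp_init <- function(d_in, hidden_sizes) {
  sizes <- c(d_in, hidden_sizes, 1L)
  n_layers <- length(sizes) - 1L
  w <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- sizes[l]
    sd <- if (l < n_layers) sqrt(2 / fan_in) else sqrt(1 / fan_in)
    w[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sd),
                     fan_in, sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(w = w, b = b)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass; when training, applies inverted dropout with fresh masks
# from the current RNG stream and returns the cached activations.
mlp_forward <- function(params, x, dropout_rate = 0, training = FALSE) {
  n_layers <- length(params$w)
  acts <- vector("list", n_layers)  # post-activation (post-dropout) inputs
  masks <- vector("list", n_layers)
  h <- x
  for (l in seq_len(n_layers)) {
    acts[[l]] <- h
    z <- h %*% params$w[[l]]
    z <- sweep(z, 2, params$b[[l]], "+")
    if (l < n_layers) {
      h <- pmax(z, 0)
      if (training && dropout_rate > 0) {
        mask <- matrix(
          stats::runif(length(h)) >= dropout_rate, nrow(h), ncol(h)
        ) / (1 - dropout_rate)
        h <- h * mask
        masks[[l]] <- mask
      }
    } else {
      h <- sigmoid(z)
    }
  }
  list(out = as.numeric(h), acts = acts, masks = masks)
}

bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Backpropagation of mean BCE through sigmoid output and ReLU hiddens.
mlp_gradients <- function(params, fwd, y) {
  n_layers <- length(params$w)
  n <- length(y)
  gw <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  delta <- matrix((fwd$out - y) / n, n, 1)  # d(mean BCE)/dz at output
  for (l in rev(seq_len(n_layers))) {
    a <- fwd$acts[[l]]
    gw[[l]] <- crossprod(a, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(params$w[[l]])
      if (!is.null(fwd$masks[[l - 1]])) delta <- delta * fwd$masks[[l - 1]]
      # ReLU derivative on the pre-dropout activation sign
      delta <- delta * (fwd$acts[[l]] > 0)
    }
  }
  list(w = gw, b = gb)
}

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mw = zero_like(params$w), vw = zero_like(params$w),
       mb = zero_like(params$b), vb = zero_like(params$b), t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params$w)) {
    state$mw[[l]] <- beta1 * state$mw[[l]] + (1 - beta1) * grads$w[[l]]
    state$vw[[l]] <- beta2 * state$vw[[l]] + (1 - beta2) * grads$w[[l]]^2
    params$w[[l]] <- params$w[[l]] -
      lr * (state$mw[[l]] / bc1) / (sqrt(state$vw[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- training --------------------------------------------------------------

#' Train the tumor/normal cell classifier
#'
#' Fits a fully connected neural network (input, hidden ReLU layers with
#' dropout, sigmoid output) on per-cell pathway activity scores by
#' minimizing binary cross-entropy with Adam. A stratified internal
#' validation fold (`val_fraction` of the training cells) drives early
#' stopping: training stops after `patience` epochs without validation
#' improvement and the best-validation weights are kept. The per-pathway
#' standardization scaler is fitted on the training scores and embedded
#' in the model, together with the pathway order, threshold, full
#' configuration and seed, so prediction is self-contained and
#' reproducible.
#'
#' @param scores Training score matrix (`pathway_scores` or
#'   pathway-by-cell matrix), typically restricted to pathways retained
#'   by [wilcoxon_filter()].
#' @param labels Training labels.
#' @param config A [training_config()].
#' @param threshold Probability cut for calling a cell tumor
#'   (default 0.5; ties go to tumor).
#' @param normalization List recording how counts were normalized before
#'   scoring (stored for provenance).
#' @return A `pathcell_model` object.
#' @export
train_model <- function(scores, labels, config = training_config(),
                        threshold = 0.5,
                        normalization = list(target_sum = 1e4,
                                             log_transform = TRUE)) {
  m <- as_score_matrix(scores)
  y <- align_labels(labels, colnames(m))
  if (length(unique(y)) < 2) input_abort("training labels contain a single class")
  check_two_classes(y)
  stopifnot(threshold > 0, threshold < 1)

  scaler <- fit_scaler(m)
  x_all <- t(apply_scaler(m, scaler))  # cells x pathways

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 1L))

  # Stratified internal validation fold for early stopping.
  val_idx <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    n_val <- max(1L, round(config$val_fraction * length(idx)))
    val_idx <- c(val_idx, sample(idx, n_val))
  }
  val_idx <- sort(val_idx)
  tr_idx <- setdiff(seq_along(y), val_idx)
  x_tr <- x_all[tr_idx, , drop = FALSE]
  y_tr <- y[tr_idx]
  x_val <- x_all[val_idx, , drop = FALSE]
  y_val <- y[val_idx]

  params <- mlp_init(ncol(x_tr), config$hidden_sizes)
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  n_tr <- nrow(x_tr)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = config$batch_size)
    for (s in starts) {
      batch <- ord[s:min(s + config$batch_size - 1L, n_tr)]
      fwd <- mlp_forward(params, x_tr[batch, , drop = FALSE],
                         config$dropout_rate, training = TRUE)
      loss <- bce_loss(fwd$out, y_tr[batch])
      if (!is.finite(loss)) {
        abort("training loss became non-finite; try a smaller learning_rate",
              class = "pathcell_training_error")
      }
      grads <- mlp_gradients(params, fwd, y_tr[batch])
      upd <- adam_step(params, grads, opt, config$learning_rate)
      params <- upd$params
      opt <- upd$state
    }
    val_loss <- bce_loss(mlp_forward(params, x_val)$out, y_val)
    if (val_loss < best$loss - 1e-7) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  structure(
    list(
      pathway_names = rownames(m),
      scaler = scaler,
      params = best$params,
      threshold = threshold,
      config = config,
      seed = config$seed,
      normalization = normalization,
      training = list(
        epochs_run = epoch,
        best_epoch = best$epoch,
        best_val_loss = best$loss,
        n_train = length(tr_idx),
        n_val = length(val_idx)
      )
    ),
    class = "pathcell_model"
  )
}

#' @export
print.pathcell_model <- function(x, ...) {
  cat(sprintf(
    paste0("<pathcell_model> %d pathways -> [%s] -> 1 (sigmoid)\n",
           "  threshold %.2f | best val BCE %.4f at epoch %d/%d | seed %d\n"),
    length(x$pathway_names),
    paste(x$config$hidden_sizes, collapse = ", "),
    x$threshold, x$training$best_val_loss, x$training$best_epoch,
    x$training$epochs_run, x$seed
  ))
  invisible(x)
}

# Align a score matrix to the model's pathway order (by name) and
# standardize it with the embedded scaler.
model_standardize <- function(model, scores) {
  m <- as_score_matrix(scores)
  missing <- setdiff(model$pathway_names, rownames(m))
  if (length(missing) > 0) {
    input_abort(paste0(
      "score matrix is missing model pathway(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  m <- m[model$pathway_names, , drop = FALSE]
  if (any(!is.finite(m))) input_abort("non-finite values in score matrix")
  (m - model$scaler$means) / model$scaler$scales
}

#' Predict tumor probability per cell
#'
#' Scores are realigned to the model's pathway order by name,
#' standardized with the embedded scaler, and passed through the network.
#' A cell is called tumor when its probability is at or above the model
#' threshold.
#'
#' @param object A `pathcell_model`.
#' @param scores Score matrix covering all model pathways (extra pathways
#'   are ignored; missing ones are an error).
#' @param standardized Set `TRUE` when `scores` is already on the
#'   standardized scale (as in the pathway-inactivation protocol); the
#'   embedded scaler is then skipped.
#' @param ... Unused.
#' @return A tibble with `barcode`, `probability`, `call`.
#' @export
predict.pathcell_model <- function(object, scores, standardized = FALSE, ...) {
  z <- if (standardized) {
    m <- as_score_matrix(scores)
    m[object$pathway_names, , drop = FALSE]
  } else {
    model_standardize(object, scores)
  }
  prob <- mlp_forward(object$params, t(z))$out
  tibble::tibble(
    barcode = colnames(z),
    probability = prob,
    call = ifelse(prob >= object$threshold, "tumor", "normal")
  )
}

#' Classification metrics with tumor as the positive class
#'
#' Precision, recall, F1 and accuracy from the confusion counts of
#' predicted versus true labels. Zero-denominator cases (no positive
#' calls, or no positive truth) report 0 for the affected metric, so
#' degenerate all-negative predictors are penalized rather than hidden.
#'
#' @param calls Predicted labels, or the prediction tibble from
#'   [predict.pathcell_model()].
#' @param truth True labels.
#' @return A one-row tibble (class `metrics_report`): `f1`, `accuracy`,
#'   `precision`, `recall`, `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_predictions <- function(calls, truth) {
  if (is.data.frame(calls) && "call" %in% names(calls)) calls <- calls$call
  yhat <- as_label01(calls)
  y <- as_label01(truth)
  if (length(yhat) != length(y)) {
    input_abort(sprintf("calls (%d) and truth (%d) differ in length",
                        length(yhat), length(y)))
  }
  tp <- sum(yhat == 1 & y == 1)
  fp <- sum(yhat == 1 & y == 0)
  tn <- sum(yhat == 0 & y == 0)
  fn <- sum(yhat == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(
    tibble::tibble(
      f1 = f1,
      accuracy = (tp + tn) / length(y),
      precision = precision,
      recall = recall,
      tp = tp, fp = fp, tn = tn, fn = fn
    ),
    class = c("metrics_report", "tbl_df", "tbl", "data.frame")
  )
}

#' Tidy a fitted cell classifier
#'
#' One row per input pathway with its standardization parameters and the
#' L2 norm of its first-layer weights (a quick view of which features the
#' network uses; for a principled measure use
#' [permutation_importance()]).
#'
#' @param x A `pathcell_model`.
#' @param ... Unused.
#' @return A tibble with `pathway`, `scaler_mean`, `scaler_scale`,
#'   `input_weight_norm`.
#' @export
tidy.pathcell_model <- function(x, ...) {
  tibble::tibble(
    pathway = x$pathway_names,
    scaler_mean = unname(x$scaler$means),
    scaler_scale = unname(x$scaler$scales),
    input_weight_norm = sqrt(rowSums(x$params$w[[1]]^2))
  )
}

#' @rdname tidy.pathcell_model
#' @return For `glance`, a one-row tibble of training metadata.
#' @export
glance.pathcell_model <- function(x, ...) {
  n_par <- sum(vapply(x$params$w, length, numeric(1))) +
    sum(vapply(x$params$b, length, numeric(1)))
  tibble::tibble(
    n_pathways = length(x$pathway_names),
    n_parameters = n_par,
    epochs_run = x$training$epochs_run,
    best_epoch = x$training$best_epoch,
    best_val_loss = x$training$best_val_loss,
    threshold = x$threshold,
    seed = x$seed
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
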