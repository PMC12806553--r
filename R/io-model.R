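# Model artifacts are a single self-describing JSON file: explicit weight
# arrays, scaler parameters, pathway names, threshold, training config and
# seed. Doubles are written as "%.17g" strings so load(save(m)) reproduces
# predictions bit-identically.

MODEL_FORMAT_VERSION <- "pathcell-model-1"

num_out <- function(x) sprintf("%.17g", as.numeric(x))
num_in <- function(x) as.numeric(x)

mat_out <- function(m) {
  list(dim = dim(m), data = num_out(as.numeric(m)))
}

mat_in <- function(obj) {
  matrix(num_in(obj$data), obj$dim[1], obj$dim[2])
}

#' Save or load a trained classifier
#'
#' The artifact is a single JSON file embedding the format version,
#' ordered pathway list, scaler, layer weights, threshold, configuration
#' and seed. Numeric values are serialized at full precision, so a
#' round trip reproduces predictions bit-identically.
#'
#' @param model A `pathcell_model`.
#' @param path File path for the artifact.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the `pathcell_model`.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "pathcell_model")) {
    input_abort("model must be a pathcell_model")
  }
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    pathway_names = model$pathway_names,
    scaler = list(
      means = num_out(model$scaler$means),
      scales = num_out(model$scaler$scales)
    ),
    weights = lapply(model$params$w, mat_out),
    biases = lapply(model$params$b, num_out),
    threshold = num_out(model$threshold),
    config = unclass(model$config),
    seed = model$seed,
    normalization = model$normalization,
    training = model$training
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) format_abort(paste0("file not found: ", path))
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      abort(paste0("model artifact unreadable (truncated or corrupt): ",
                   conditionMessage(e)),
            class = c("pathcell_integrity_error", "pathcell_error"))
    }
  )
  if (is.null(obj$format_version) ||
      !identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    abort(sprintf("unsupported model format version '%s' (expected '%s')",
                  obj$format_version %||% "<missing>", MODEL_FORMAT_VERSION),
          class = c("pathcell_version_error", "pathcell_error"))
  }
  required <- c("pathway_names", "scaler", "weights", "biases", "threshold")
  miss <- setdiff(required, names(obj))
  if (length(miss) > 0) {
    abort(paste0("model artifact missing field(s): ",
                 paste(miss, collapse = ", ")),
          class = c("pathcell_integrity_error", "pathcell_error"))
  }
  pathways <- obj$pathway_names
  w <- if (is.data.frame(obj$weights)) {
    lapply(seq_len(nrow(obj$weights)), function(i) {
      mat_in(list(dim = obj$weights$dim[[i]], data = obj$weights$data[[i]]))
    })
  } else {
    lapply(obj$weights, mat_in)
  }
  b <- lapply(obj$biases, num_in)
  cfg <- obj$config
  cfg$hidden_sizes <- as.integer(cfg$hidden_sizes)
  config <- do.call(training_config, cfg)
  structure(
    list(
      pathway_names = pathways,
      scaler = list(
        means = stats::setNames(num_in(obj$scaler$means), pathways),
        scales = stats::setNames(num_in(obj$scaler$scales), pathways)
      ),
      params = list(w = w, b = b),
      threshold = num_in(obj$threshold),
      config = config,
      seed = obj$seed,
      normalization = obj$normalization,
      training = obj$training
    ),
    class = "pathcell_model"
  )
}
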