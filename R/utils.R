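# Internal helpers shared across modules.

#' @importFrom rlang abort %||%
#' @importFrom methods as is
NULL

format_abort <- function(msg, class = "pathcell_format_error") {
  abort(msg, class = c(class, "pathcell_error"))
}

input_abort <- function(msg) {
  abort(msg, class = c("pathcell_input_error", "pathcell_error"))
}

# Deterministic 31-bit seed derived from a base seed and integer tags, so
# per-(unit, repeat) random draws are reproducible and order-independent.
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (k in as.double(c(...))) {
    h <- (h * 48271 + k + 1) %% 2147483647
  }
  as.integer(h)
}

# Canonical gene-symbol form used for matching counts against gene sets.
canonical_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# Coerce a label input (character tumor/normal, factor, logical, or 0/1) to
# an integer vector with tumor = 1, normal = 0.
as_label01 <- function(labels) {
  if (is.data.frame(labels)) {
    if (!"label" %in% names(labels)) {
      input_abort("label data frame must have a 'label' column")
    }
    labels <- labels$label
  }
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lab <- tolower(trimws(labels))
    bad <- setdiff(unique(lab), c("tumor", "normal"))
    if (length(bad) > 0) {
      input_abort(paste0(
        "labels must be 'tumor' or 'normal'; found: ",
        paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
    return(as.integer(lab == "tumor"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      input_abort("numeric labels must be 0 (normal) or 1 (tumor)")
    }
    return(as.integer(labels))
  }
  input_abort("unsupported label type")
}

label_names <- function(label01) {
  c("normal", "tumor")[label01 + 1L]
}

check_two_classes <- function(y, min_per_class = 2L) {
  tab <- tabulate(y + 1L, nbins = 2L)
  if (any(tab < min_per_class)) {
    input_abort(sprintf(
      "both classes required with >= %d cells each (got %d normal, %d tumor)",
      min_per_class, tab[1], tab[2]
    ))
  }
  invisible(tab)
}
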