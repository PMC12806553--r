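#' Configuration for the synthetic scRNA-seq generator
#'
#' Parameters of the negative-binomial generative model with planted
#' pathway-level tumor effects. Genes are partitioned into non-overlapping
#' pathways; per-gene baseline means are lognormal; in tumor cells the
#' genes of "up" pathways have their means multiplied by
#' `2^effect_log2fc` and "down" pathways by `2^-effect_log2fc` (the
#' metabolic-up / immune-down structure of real tumors); counts are
#' negative binomial with the given dispersion; tumor cells draw from
#' means scaled by `tumor_library_scale`, reproducing the observation
#' that tumor cells detect more genes than normal cells; finally each
#' entry is zeroed with probability
#' `logistic(-dropout_slope * (log(mean) - dropout_midpoint))`, the
#' standard mean-dependent dropout model.
#'
#' @param n_tumor,n_normal Cells per class.
#' @param n_genes Number of genes.
#' @param n_pathways Number of pathways.
#' @param genes_per_pathway Length-2 integer range of pathway sizes.
#' @param n_up_pathways,n_down_pathways Pathways planted up/down in tumor
#'   cells.
#' @param effect_log2fc Planted log2 effect size (> 0 unless running a
#'   null simulation with 0).
#' @param baseline_mean_log_mu,baseline_mean_log_sd Lognormal parameters
#'   of per-gene baseline means (natural-log scale).
#' @param dispersion Negative-binomial size parameter (smaller = noisier).
#' @param tumor_library_scale Multiplier (>= 1) on tumor-cell means.
#' @param dropout_midpoint,dropout_slope Logistic dropout parameters on
#'   the log-mean scale.
#' @param seed RNG seed; generation is fully deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_tumor = 500L, n_normal = 500L,
                              n_genes = 5000L, n_pathways = 100L,
                              genes_per_pathway = c(25L, 60L),
                              n_up_pathways = 10L, n_down_pathways = 10L,
                              effect_log2fc = 1,
                              baseline_mean_log_mu = -1.5,
                              baseline_mean_log_sd = 1,
                              dispersion = 0.5,
                              tumor_library_scale = 1.5,
                              dropout_midpoint = -1,
                              dropout_slope = 1,
                              seed = 1L) {
  stopifnot(
    n_tumor >= 1, n_normal >= 1, n_genes >= 1, n_pathways >= 1,
    length(genes_per_pathway) == 2, genes_per_pathway[1] >= 1,
    genes_per_pathway[2] >= genes_per_pathway[1],
    n_up_pathways >= 0, n_down_pathways >= 0,
    effect_log2fc >= 0, dispersion > 0, tumor_library_scale >= 1,
    baseline_mean_log_sd >= 0, dropout_slope >= 0
  )
  if (n_up_pathways + n_down_pathways > n_pathways) {
    input_abort("n_up_pathways + n_down_pathways must not exceed n_pathways")
  }
  if (genes_per_pathway[1] * n_pathways > n_genes) {
    input_abort("n_genes too small for n_pathways at the minimum pathway size")
  }
  structure(
    list(
      n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
      n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
      genes_per_pathway = as.integer(genes_per_pathway),
      n_up_pathways = as.integer(n_up_pathways),
      n_down_pathways = as.integer(n_down_pathways),
      effect_log2fc = effect_log2fc,
      baseline_mean_log_mu = baseline_mean_log_mu,
      baseline_mean_log_sd = baseline_mean_log_sd,
      dispersion = dispersion,
      tumor_library_scale = tumor_library_scale,
      dropout_midpoint = dropout_midpoint,
      dropout_slope = dropout_slope,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Generate a labeled synthetic scRNA-seq dataset
#'
#' Draws a count matrix, gene-set collection and ground truth from the
#' generative model described in [simulation_config()]. With
#' `effect_log2fc = 0` and `tumor_library_scale = 1` the two classes are
#' exchangeable — the global-null configuration used for calibration
#' checks.
#'
#' @param config A [simulation_config()].
#' @return A list with `counts` (sparse gene-by-cell matrix), `gene_sets`
#'   (named list), `labels` (tibble: `barcode`, `label`), and `truth`
#'   (list: `up_pathways`, `down_pathways`, `gene_means` tibble with
#'   per-class true means).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 2024L))

  genes <- sprintf("G%05d", seq_len(config$n_genes))
  pw_names <- sprintf("PW%04d", seq_len(config$n_pathways))

  sizes <- sample(seq(config$genes_per_pathway[1], config$genes_per_pathway[2]),
                  config$n_pathways, replace = TRUE)
  if (sum(sizes) > config$n_genes) {
    input_abort("sampled pathway sizes exceed n_genes; increase n_genes")
  }
  shuffled <- sample(genes)
  ends <- cumsum(sizes)
  gene_sets <- stats::setNames(
    lapply(seq_along(sizes), function(i) {
      sort(shuffled[(ends[i] - sizes[i] + 1):ends[i]])
    }),
    pw_names
  )

  planted <- sample(pw_names, config$n_up_pathways + config$n_down_pathways)
  up <- planted[seq_len(config$n_up_pathways)]
  down <- setdiff(planted, up)

  base_mu <- stats::rlnorm(config$n_genes,
                           meanlog = config$baseline_mean_log_mu,
                           sdlog = config$baseline_mean_log_sd)
  names(base_mu) <- genes
  mu_tumor <- base_mu
  fc <- 2^config$effect_log2fc
  mu_tumor[unlist(gene_sets[up], use.names = FALSE)] <-
    mu_tumor[unlist(gene_sets[up], use.names = FALSE)] * fc
  mu_tumor[unlist(gene_sets[down], use.names = FALSE)] <-
    mu_tumor[unlist(gene_sets[down], use.names = FALSE)] / fc
  mu_tumor <- mu_tumor * config$tumor_library_scale

  block <- function(mu, n_cells) {
    m <- matrix(
      stats::rnbinom(config$n_genes * n_cells, mu = mu, size = config$dispersion),
      nrow = config$n_genes
    )
    p_drop <- stats::plogis(
      -config$dropout_slope * (log(mu) - config$dropout_midpoint)
    )
    drop <- matrix(
      stats::runif(length(m)) < p_drop, nrow = config$n_genes
    )
    m[drop] <- 0L
    m
  }
  counts <- cbind(block(mu_tumor, config$n_tumor),
                  block(base_mu, config$n_normal))
  dimnames(counts) <- list(genes, c(
    sprintf("tumor_%04d", seq_len(config$n_tumor)),
    sprintf("normal_%04d", seq_len(config$n_normal))
  ))
  counts <- as(as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
               "generalMatrix")

  labels <- tibble::tibble(
    barcode = colnames(counts),
    label = rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
  )
  truth <- list(
    up_pathways = up,
    down_pathways = down,
    gene_means = tibble::tibble(
      gene = genes,
      mean_normal = unname(base_mu),
      mean_tumor = unname(mu_tumor)
    )
  )
  list(counts = counts, gene_sets = gene_sets, labels = labels,
       truth = truth, config = config)
}

#' The frozen acceptance dataset
#'
#' The fixed benchmark configuration used throughout the package's
#' end-to-end checks: 1,000 tumor + 1,000 normal cells, 5,000 genes, 100
#' pathways of 25-60 genes, 10 up- and 10 down-planted pathways at
#' `effect_log2fc` 1.0, dispersion 0.5, tumor library scale 1.5. Also
#' returns the stratified 8:2 train/test split indices.
#'
#' @param seed RNG seed for generation and the split.
#' @return The [generate_dataset()] bundle plus a `split` element with
#'   `train` and `test` index vectors.
#' @export
make_acceptance_dataset <- function(seed = 1L) {
  cfg <- simulation_config(
    n_tumor = 1000L, n_normal = 1000L,
    n_genes = 5000L, n_pathways = 100L,
    genes_per_pathway = c(25L, 60L),
    n_up_pathways = 10L, n_down_pathways = 10L,
    effect_log2fc = 1,
    dispersion = 0.5,
    tumor_library_scale = 1.5,
    seed = seed
  )
  ds <- generate_dataset(cfg)
  ds$split <- split_data(ds$labels, split_ratio = 0.8, seed = seed)
  ds
}

#' Write a generated dataset to disk
#'
#' Emits the 10x-style MatrixMarket directory, the GMT file, the label
#' TSV and a truth TSV, so generated data doubles as an I/O round-trip
#' fixture.
#'
#' @param dataset A [generate_dataset()] bundle.
#' @param path Output directory.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_10x_counts(dataset$counts, file.path(path, "counts"))
  write_gmt(dataset$gene_sets, file.path(path, "pathways.gmt"))
  write_labels(dataset$labels, file.path(path, "labels.tsv"))
  truth <- tibble::tibble(
    pathway = c(dataset$truth$up_pathways, dataset$truth$down_pathways),
    direction = rep(c("up", "down"),
                    c(length(dataset$truth$up_pathways),
                      length(dataset$truth$down_pathways)))
  )
  utils::write.table(truth, file.path(path, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
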