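#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a robustness curve
#'
#' Per-level mean F1 with a mean +/- SD ribbon across replicate
#' degradation draws.
#'
#' @param object A `robustness_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.robustness_curve <- function(object, ...) {
  s <- tidy(object)
  xlab <- if (unique(s$protocol) == "gene_retention") {
    "genes retained per cell"
  } else {
    "fraction of pathways inactivated"
  }
  ggplot2::ggplot(s, ggplot2::aes(x = .data$level, y = .data$f1_mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$f1_mean - .data$f1_sd,
                   ymax = .data$f1_mean + .data$f1_sd),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = "F1 (tumor positive)") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot a permutation importance table
#'
#' Mean loss increase (with SD error bars) for the `top_n` most important
#' pathways.
#'
#' @param object An `importance_table`.
#' @param top_n Number of pathways shown (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_table <- function(object, top_n = 20, ...) {
  d <- dplyr::slice_min(tibble::as_tibble(object), .data$rank, n = top_n)
  d$pathway <- stats::reorder(d$pathway, -d$rank)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_delta_loss, y = .data$pathway)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean_delta_loss - .data$sd_delta_loss,
                   xmax = .data$mean_delta_loss + .data$sd_delta_loss),
      height = 0.3
    ) +
    ggplot2::labs(x = "mean loss increase under shuffling", y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential pathway results
#'
#' @param results Tibble from [differential_pathways()].
#' @param lfc_threshold,fdr_threshold Guide lines matching the flagging
#'   rule.
#' @return A ggplot.
#' @export
plot_differential_pathways <- function(results, lfc_threshold = 1,
                                       fdr_threshold = 0.05) {
  ggplot2::ggplot(
    results,
    ggplot2::aes(x = .data$log2fc, y = -log10(pmax(.data$fdr, 1e-300)),
                 color = .data$flagged)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(fdr_threshold),
                        linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (tumor / normal)",
                  y = "-log10 FDR", color = "flagged") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
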