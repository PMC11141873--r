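# ggplot2 views of the three result types. Each autoplot() returns the
# ggplot object unevaluated so callers can restyle it.

#' Plot a correlation screen
#'
#' Histogram of Spearman rho across the gene universe, with the selected
#' correlated set overlaid when supplied.
#'
#' @param object A `coexmotif_correlations` tibble.
#' @param gene_set Optional `coexmotif_gene_set` to highlight.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.coexmotif_correlations <- function(object, gene_set = NULL, ...) {
  p <- ggplot(object, aes(x = .data$rho)) +
    geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "Spearman rho with seed gene", y = "genes",
         title = paste0("Seed-gene correlation screen (",
                        attr(object, "seed_gene_id") %||% "seed", ")"))
  if (!is.null(gene_set) && nrow(gene_set)) {
    p <- p + geom_histogram(data = as_tibble(gene_set), bins = 60,
                            fill = "firebrick", alpha = 0.7)
  }
  p
}

#' Plot a motif-enrichment screen
#'
#' Effect size versus significance per motif ("volcano"), faceted by window
#' size when several window families are present; the FDR 0.05 line is drawn
#' for orientation.
#'
#' @param object A `coexmotif_screen` tibble (or the combined `enrichment`
#'   tibble of a [run_screen()] result).
#' @param fdr_line FDR threshold drawn as a reference (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.coexmotif_screen <- function(object, fdr_line = 0.05, ...) {
  d <- as_tibble(object) |>
    mutate(neglog_p = -log10(pmax(.data$p_value, 1e-300)),
           significant = .data$fdr < fdr_line)
  p <- ggplot(d, aes(x = .data$effect, y = .data$neglog_p,
                     colour = .data$significant)) +
    geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "motif effect (log-odds)", y = "-log10 p",
         title = "Promoter motif enrichment")
  if (length(unique(d$window_bp)) > 1) {
    p <- p + facet_wrap(~window_bp, labeller = ggplot2::label_both)
  }
  p
}

#' Plot predicted targets for a motif
#'
#' Horizontal bar chart of the combined rank-product score of the top
#' predicted target genes, best at the top.
#'
#' @param object A `coexmotif_targets` tibble from [predict_targets()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.coexmotif_targets <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(gene_id = stats::reorder(.data$gene_id, -.data$rank))
  ggplot(d, aes(x = .data$combined_score, y = .data$gene_id)) +
    geom_col(fill = "steelblue") +
    labs(x = "combined score (geometric mean of quantiles)", y = NULL,
         title = paste0("Predicted targets: ", object$motif_id[1]))
}

#' @rdname autoplot.coexmotif_screen
#' @param x Screen result tibble.
#' @export
plot_enrichment <- function(x, fdr_line = 0.05) autoplot.coexmotif_screen(x, fdr_line)

#' @rdname autoplot.coexmotif_correlations
#' @param x Correlation screen tibble.
#' @export
plot_correlation_screen <- function(x, gene_set = NULL) {
  autoplot.coexmotif_correlations(x, gene_set)
}

#' @rdname autoplot.coexmotif_targets
#' @param x Target score tibble.
#' @export
plot_targets <- function(x) autoplot.coexmotif_targets(x)
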