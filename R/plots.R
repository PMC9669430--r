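# ggplot2 views of the main result types. The pipeline itself emits tables;
# these helpers render the conventional figures from them.

#' Volcano plot of DE calls
#'
#' @param x An `lnc_de` object.
#' @return A ggplot.
#' @export
plot_volcano <- function(x) {
  stopifnot(inherits(x, "lnc_de"))
  tab <- filter(x$table, !is.na(.data$p_value))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(pmax(.data$p_value, 1e-300)),
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey60")) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(x$fc_cut), linetype = 2) +
    ggplot2::labs(x = "log2 fold change (group 2 vs group 1)",
                  y = "-log10 p", colour = NULL)
}

#' Positional-class distribution of identified lncRNAs
#'
#' @param class_counts Output of [class_count_table()].
#' @return A ggplot.
#' @export
plot_class_distribution <- function(class_counts) {
  ggplot2::ggplot(class_counts,
                  ggplot2::aes(x = .data$class, y = .data$n, fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "lncRNAs") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Sample-correlation heatmap
#'
#' @param corr Output of [sample_correlation()].
#' @return A ggplot.
#' @export
plot_correlation <- function(corr) {
  long <- tidyr::pivot_longer(corr, -"sample", names_to = "sample2",
                              values_to = "r")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$sample2,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#c0392b",
                                 limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r")
}

#' Enrichment scatter (rich factor vs term)
#'
#' @param top Output of [top_terms()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(top) {
  ggplot2::ggplot(top, ggplot2::aes(x = .data$rich_factor,
                                    y = stats::reorder(.data$name, -.data$p_value),
                                    size = .data$k, colour = .data$q_value)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "#c0392b", high = "#2980b9") +
    ggplot2::labs(x = "rich factor (k / K)", y = NULL, size = "hits",
                  colour = "q value")
}
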