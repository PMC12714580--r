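# ggplot2 displays for the main result types.

#' Region profile bar chart
#'
#' Percentage of integration sites per genomic region and sample.
#'
#' @param x A [region_summaries()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_summary <- function(x, ...) {
  ggplot2::ggplot(x$region_pct,
                  ggplot2::aes(x = .data$sample, y = .data$pct,
                               fill = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of integration sites", fill = "region") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a moderated differential-expression table
#'
#' @param de A [ebayes_moderate()] table.
#' @param lfc,alpha Thresholds drawn as guides and used for colouring.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, lfc = 1, alpha = 0.01) {
  d <- de |>
    mutate(status = dplyr::case_when(
      .data$log2fc > lfc & .data$p_adj < alpha ~ "up",
      .data$log2fc < -lfc & .data$p_adj < alpha ~ "down",
      TRUE ~ "ns"
    ))
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, -log10(.data$p),
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' Gene ratio against set, dot size = overlap, colour = adjusted p —
#' the standard over-representation display.
#'
#' @param enrichment An [ora()] result tibble.
#' @param max_sets Show at most this many sets (by p).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, max_sets = 20L) {
  d <- enrichment |>
    arrange(.data$p) |>
    head(max_sets) |>
    mutate(set_name = factor(.data$set_name, rev(unique(.data$set_name))))
  ggplot2::ggplot(d, ggplot2::aes(.data$gene_ratio, .data$set_name,
                                  size = .data$k, colour = .data$p_adj)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "firebrick", high = "steelblue") +
    ggplot2::labs(x = "gene ratio", y = NULL, size = "overlap",
                  colour = "BH p") +
    ggplot2::theme_minimal()
}

#' Signature score summary plot
#'
#' Group means with SEM error bars.
#'
#' @param score_means An [average_scores()] tibble with a `group` column.
#' @return A ggplot object.
#' @export
plot_signature_scores <- function(score_means) {
  ggplot2::ggplot(score_means,
                  ggplot2::aes(.data$group, .data$mean_score)) +
    ggplot2::geom_col(fill = "grey80") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_score - .data$sem,
                   ymax = .data$mean_score + .data$sem), width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean signature score (± SEM)") +
    ggplot2::theme_minimal()
}

#' Module-trait correlation heatmap
#'
#' @param mtc A [module_trait_correlation()] tibble.
#' @return A ggplot object.
#' @export
plot_module_trait <- function(mtc) {
  ggplot2::ggplot(mtc, ggplot2::aes(.data$trait, .data$module,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.2g)", .data$r, .data$p)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Methylation region-count heatmap
#'
#' log2 counts of hyper/hypo calls per position class and CpG class.
#'
#' @param region_tab A [summarize_by_region()] tibble.
#' @return A ggplot object.
#' @export
plot_methylation_regions <- function(region_tab) {
  ggplot2::ggplot(region_tab,
                  ggplot2::aes(.data$position_class, .data$cpg_class,
                               fill = .data$log2_n)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~ .data$state) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2(n+1)") +
    ggplot2::theme_minimal()
}
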