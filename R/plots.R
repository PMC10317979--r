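# Diagnostic ggplot2 figures for the main result types.

#' Plot composition trends over stages
#'
#' Mean composition percentage per stage and group, one line per group,
#' faceted by category.
#'
#' @param profiles Output of [composition_percent()].
#' @param group Grouping column (default `"macro_region"`).
#' @return A ggplot.
#' @export
plot_composition <- function(profiles, group = "macro_region") {
  df <- profiles |>
    group_by(stage = stage_factor(.data$stage),
             group = .data[[group]], .data$category) |>
    summarise(percent = mean(.data$percent), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$percent,
                                   colour = .data$group,
                                   group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free_y") +
    ggplot2::labs(x = "stage", y = "% of total LFQ intensity",
                  colour = group) +
    ggplot2::theme_minimal()
}

#' Plot the inter-regional difference curve
#'
#' @param curve Output of [interregional_curve()].
#' @return A ggplot.
#' @export
plot_interregional <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(stage_factor(.data$stage),
                                      .data$value,
                                      colour = .data$group,
                                      group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "stage", y = "mean |log2 difference|",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Scatter plot of RNA vs protein fold changes by concordance type
#'
#' @param typed Output of [classify_six_types()].
#' @return A ggplot on log2 axes with the |FC| = 2 guides.
#' @export
plot_concordance <- function(typed) {
  ggplot2::ggplot(typed, ggplot2::aes(log2(.data$fc_rna),
                                      log2(.data$fc_protein),
                                      colour = factor(.data$type))) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "log2 FC (RNA)", y = "log2 FC (protein)",
                  colour = "type") +
    ggplot2::theme_minimal()
}

#' Histogram of ortholog correlations per species comparison
#'
#' @param dist Output of [correlation_distribution()].
#' @return A ggplot of binned percentages with the cumulative curve.
#' @export
plot_correlation_distribution <- function(dist) {
  ggplot2::ggplot(dist$histogram,
                  ggplot2::aes(.data$bin_mid, .data$percent,
                               fill = .data$comparison)) +
    ggplot2::geom_col(position = "dodge", width = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_percent,
                                    colour = .data$comparison),
                       linewidth = 0.7) +
    ggplot2::labs(x = "Pearson r", y = "% of orthologs") +
    ggplot2::theme_minimal()
}
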