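# ggplot2 quick-look figures for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Correlation fingerprint plot
#'
#' Per-bin Pearson r against ppm, coloured by significance class, the way
#' medium-fingerprint correlation profiles are usually displayed (ppm axis
#' reversed).
#'
#' @param object A `correlation_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ppm, y = .data$r,
                                   colour = .data$class)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$ppm, yend = 0),
                          linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_colour_manual(values = c(
      strong = "#c0392b", weak = "grey30", none = "grey80",
      undefined = "grey95")) +
    ggplot2::labs(x = "chemical shift (ppm)", y = "Pearson r",
                  colour = "significance") +
    ggplot2::theme_minimal()
}

#' Fed-batch trajectory plot
#'
#' Biomass, substrate, inhibitor and feed rate over the feeding phase.
#'
#' @param object A `fedbatch_sim` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fedbatch_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("time_h", "biomass_g_per_L", "substrate", "inhibitor",
               "feed_rate")],
    -"time_h", names_to = "variable", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time since feed onset (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Pathway coverage heat table
#'
#' @param object A `coverage_table` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pathway, .data$sample,
                                       fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(.data$count, " (", .data$percent, "%)")), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = NULL, fill = "% of pathway") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Per-chromosome density plot
#'
#' @param object A `density_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$chrom, levels = .data$chrom),
    y = .data$density_per_mbp, fill = .data$is_mito)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$nuclear_mean,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "#c0392b"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "fragments per Mbp") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
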