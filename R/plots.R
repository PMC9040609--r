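# ggplot2 visualisations for the main result types.

#' Plot growth and survival curves
#'
#' OD (log scale) and CFU/mL per condition, colour-coded by light regime.
#'
#' @param curves [simulate_growth_all()]-shaped tibble.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(curves) {
  long <- curves %>%
    tidyr::pivot_longer(c("od", "cfu_ml"), names_to = "measure",
                        values_to = "value") %>%
    mutate(measure = dplyr::recode(.data$measure, od = "OD660",
                                   cfu_ml = "CFU/mL"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$time_h, y = .data$value,
                               colour = .data$light,
                               group = interaction(.data$light,
                                                   .data$replicate))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(measure ~ condition, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = NULL, colour = "Light") +
    ggplot2::theme_minimal()
}

#' Plot proteorhodopsin copies per cell over time
#'
#' @param pr_consolidated [pr_consolidate()] output.
#' @return A ggplot object.
#' @export
plot_pr_copies <- function(pr_consolidated) {
  ggplot2::ggplot(pr_consolidated,
                  ggplot2::aes(x = .data$timepoint_h, y = .data$mean_copies,
                               colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_copies - .data$sd_copies,
      ymax = .data$mean_copies + .data$sd_copies)) +
    ggplot2::labs(x = "Time (h)", y = "PR copies per cell",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a moderated differential-expression fit
#'
#' @param object A `moderated_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot moderated_fit
#' @export
autoplot.moderated_fit <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$effect,
                                    y = -log10(.data$p_value),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      title = if (!is.null(object$contrast)) object$contrast$name else NULL,
      x = "log2 fold change", y = "-log10 p",
      colour = "BH < 0.05"
    ) +
    ggplot2::theme_minimal()
}

#' Plot qPCR relative-expression time courses
#'
#' @param rel [qpcr_relative()]-shaped tibble with `gene` column.
#' @return A ggplot object.
#' @export
plot_qpcr <- function(rel) {
  ggplot2::ggplot(rel,
                  ggplot2::aes(x = .data$timepoint_h,
                               y = .data$rel_expression,
                               colour = .data$light,
                               group = interaction(.data$light,
                                                   .data$replicate))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_grid(gene ~ condition, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = "Expression relative to recA",
                  colour = "Light") +
    ggplot2::theme_minimal()
}
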