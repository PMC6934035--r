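#' Rating histograms per instruction condition
#'
#' Side-by-side histograms of responses under the two instruction
#' conditions; grammaticality instructions typically produce the more
#' extreme, U-shaped distribution.
#'
#' @param records Rating records.
#' @param binwidth Histogram bin width (1 suits the 0--5 integer scale).
#' @return A ggplot object.
#' @export
plot_rating_histograms <- function(records, binwidth = 1) {
  records <- dplyr::filter(tibble::as_tibble(records),
                           !.data$is_attention_check)
  ggplot2::ggplot(records, ggplot2::aes(x = .data$rating)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = -0.5,
                            fill = "grey40") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "rating (0-5)", y = "responses") +
    ggplot2::theme_minimal()
}

#' @describeIn contrast_table Dot plot of condition means with 95%
#'   confidence intervals, one panel pair per sentence type.
#' @param object A `contrast_table`.
#' @param ... Unused.
#' @method autoplot contrast_table
#' @export
autoplot.contrast_table <- function(object, ...) {
  long <- object |>
    dplyr::mutate(unit = paste(.data$sentence_type, .data$variant,
                               sep = "\n")) |>
    tidyr::pivot_longer(
      cols = c("mean_acceptability", "mean_grammaticality"),
      names_to = "condition", names_prefix = "mean_", values_to = "mean"
    ) |>
    dplyr::mutate(ci = ifelse(.data$condition == "acceptability",
                              .data$ci_acceptability,
                              .data$ci_grammaticality))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean, y = .data$unit,
                                     colour = .data$condition)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean - .data$ci,
                   xmax = .data$mean + .data$ci),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::labs(x = "mean rating (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Violin plot of per-item rating differences
#'
#' One violin per sentence type x variant, showing the distribution of
#' per-item acceptability-minus-grammaticality differences from
#' [difference_distributions()].
#'
#' @param diffs Output of [difference_distributions()].
#' @return A ggplot object.
#' @export
plot_difference_violins <- function(diffs) {
  diffs <- dplyr::mutate(diffs, unit = paste(.data$sentence_type,
                                             .data$variant, sep = "\n"))
  ggplot2::ggplot(diffs, ggplot2::aes(x = .data$unit, y = .data$diff)) +
    ggplot2::geom_violin(fill = "grey80") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL,
                  y = "acceptability - grammaticality (per item)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn sta_test State-trace plot: per-unit grammaticality mean
#'   against acceptability mean, with the fitted one-dimensional monotone
#'   trace overlaid in the best common order.
#' @param object An `sta_result`.
#' @method autoplot sta_result
#' @export
autoplot.sta_result <- function(object, ...) {
  td <- tidy(object)
  trace <- td[order(td$position), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = trace,
                       ggplot2::aes(x = .data$fitted_x, y = .data$fitted_y),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$wx), alpha = 0.7) +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::labs(
      x = "mean acceptability rating", y = "mean grammaticality rating",
      title = sprintf("State trace (statistic %.3g, p = %.2g)",
                      object$observed_statistic, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn power_curve Strip plot of simulated p values against latent
#'   correlation, with the alpha threshold marked.
#' @param object A `power_curve`.
#' @param ... Unused.
#' @method autoplot power_curve
#' @export
autoplot.power_curve <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  long <- tidyr::unnest(object, "p_values")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$rho),
                                     y = .data$p_values)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = alpha, colour = "red") +
    ggplot2::labs(x = "latent correlation", y = "p value") +
    ggplot2::theme_minimal()
}
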