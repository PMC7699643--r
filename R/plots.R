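# ggplot2 views of the scan results.

#' Manhattan-style plot of the exposure scan
#'
#' Exposures ordered by hazard ratio on the x axis, `-log10(p)` on the y
#' axis; the dotted line marks nominal p = 0.05 and the solid line the
#' permutation-FDR threshold when available.
#'
#' @param results An `ewas_results` tibble.
#' @param alpha_star Optional FDR-derived p-value threshold.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, alpha_star = NA_real_) {
  tab <- manhattan_table(results, alpha_star)
  gg <- ggplot2::ggplot(
    tab,
    ggplot2::aes(
      x = hr_rank, y = neg_log10_p, colour = direction, shape = type
    )
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(negative = "#1b9e47", positive = "#d62728")
    ) +
    ggplot2::geom_hline(
      yintercept = -log10(0.05), linetype = "dotted", colour = "red"
    ) +
    ggplot2::labs(
      x = "exposures ordered by hazard ratio",
      y = expression(-log[10] ~ "p value")
    ) +
    ggplot2::theme_minimal()
  if (is.finite(alpha_star)) {
    gg <- gg + ggplot2::geom_hline(
      yintercept = -log10(alpha_star), colour = "red"
    )
  }
  gg
}

#' @method autoplot ewas_results
#' @export
autoplot.ewas_results <- function(object, ...) {
  est <- attr(object, "fdr_estimate")
  plot_manhattan(object, if (!is.null(est)) est$alpha_star else NA_real_)
}

#' Actual versus food-implied nutrient hazard ratios
#'
#' @param decomposition A `nutrient_decomposition` tibble from
#'   [compare_actual_vs_expected()].
#' @return A ggplot object (log-log scatter with the agreement quadrants).
#' @export
plot_actual_vs_expected <- function(decomposition) {
  ggplot2::ggplot(
    decomposition,
    ggplot2::aes(x = actual_hr, y = expected_hr, colour = agree)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#1f77b4", `FALSE` = "#ff7f0e")
    ) +
    ggplot2::labs(
      x = "actual nutrient HR", y = "food-implied (expected) HR",
      colour = "same side of 1"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot nutrient_decomposition
#' @export
autoplot.nutrient_decomposition <- function(object, ...) {
  plot_actual_vs_expected(object)
}
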