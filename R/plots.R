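#' Plot pooled per-Mg potentials
#'
#' Bar chart of the pooled baseline potentials per Mg of grain with 95%
#' confidence intervals, facetted by impact class.
#'
#' @param pooled Output of [pool_baseline_impacts()].
#' @return A ggplot object.
#' @export
plot_pooled_impacts <- function(pooled) {
  ggplot2::ggplot(pooled, ggplot2::aes(
    x = .data$crop, y = .data$es_bar, fill = .data$crop
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lb, ymax = .data$ci_ub),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~impact, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "Pooled potential per Mg grains",
      title = "Yield-scaled environmental potentials (baseline practice)"
    ) +
    ggplot2::theme_minimal()
}
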