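#' Strategy effect as a percent of baseline
#'
#' \deqn{\mathrm{effect}\,(\%) = 100\,(D_b - D_s)/D_b} where \eqn{D_b} and
#' \eqn{D_s} are the pooled means under the baseline and the strategy.
#' Positive values mean the strategy decreases the quantity below the
#' baseline; negative values mean an increase.
#'
#' @param d_baseline Baseline pooled mean, non-zero.
#' @param d_strategy Strategy pooled mean.
#' @return Percent effect.
#' @examples
#' strategy_effect_pct(100, 75) # 25% decrease
#' @export
strategy_effect_pct <- function(d_baseline, d_strategy) {
  if (any(is.na(d_baseline)) || any(d_baseline == 0)) {
    abort("baseline mean must be non-zero", class = "nrimpact_domain_error")
  }
  100 * (d_baseline - d_strategy) / d_baseline
}

#' Propagate a percent effect to a national total
#'
#' \deqn{T_s = T_b - T_b \cdot \mathrm{effect}(\%)/100.} A 0% effect leaves
#' the total unchanged; 100% removes it entirely; negative effects raise it.
#'
#' @param t_baseline Baseline national total (Tg, or Gg for AEP), >= 0.
#' @param effect_pct Percent effect from [strategy_effect_pct()].
#' @return The total under the strategy, same units as `t_baseline`.
#' @export
apply_strategy <- function(t_baseline, effect_pct) {
  if (any(is.na(t_baseline)) || any(t_baseline < 0)) {
    abort("baseline total must be >= 0", class = "nrimpact_domain_error")
  }
  t_baseline * (1 - effect_pct / 100)
}

#' Couple strategy pools with baseline pools and national totals
#'
#' For every (crop, strategy, outcome) combination, expresses the strategy's
#' pooled mean as a percent of the baseline pooled mean and propagates that
#' percent to the baseline national total. Outcomes are grain yield and the
#' three potentials. Groups with fewer than `min_k` comparisons are emitted
#' as explicit rejected rows (no numeric effect) rather than dropped,
#' mirroring how sparse comparisons are excluded from a meta-analysis.
#'
#' @param strategy_pools Tibble with columns `crop`, `strategy`, `outcome`
#'   (`yield`, `AP`, `GWP`, `AEP`), `k`, `d` (pooled mean under the
#'   strategy) and optionally `Q_p` (heterogeneity p, logged through).
#' @param baseline_pools Tibble with `crop`, `outcome`, `d` (baseline pooled
#'   mean) and optionally `k`.
#' @param baseline_totals Tibble with `crop`, `outcome`, `total` — the
#'   baseline national totals (yield in Tg, AP/GWP in Tg, AEP in Gg).
#' @param min_k Minimum comparisons per strategy group, default 3.
#' @return Tibble of class `nr_strategy_effects`: one row per (crop,
#'   strategy, outcome) with `effect_pct`, `baseline_total`,
#'   `strategy_total`, `delta` (`strategy_total - baseline_total`) and
#'   `rejected`.
#' @export
couple_strategies <- function(strategy_pools, baseline_pools, baseline_totals,
                              min_k = 3) {
  need <- c("crop", "strategy", "outcome", "k", "d")
  miss <- setdiff(need, names(strategy_pools))
  if (length(miss) > 0) {
    abort(paste0("strategy_pools lacks column(s): ", paste(miss, collapse = ", ")),
      class = "nrimpact_schema_error"
    )
  }
  if (!"Q_p" %in% names(strategy_pools)) strategy_pools$Q_p <- NA_real_
  joined <- strategy_pools |>
    dplyr::left_join(
      dplyr::select(baseline_pools, "crop", "outcome", d_baseline = "d"),
      by = c("crop", "outcome")
    ) |>
    dplyr::left_join(
      dplyr::select(baseline_totals, "crop", "outcome", baseline_total = "total"),
      by = c("crop", "outcome")
    )
  if (any(is.na(joined$d_baseline)) || any(is.na(joined$baseline_total))) {
    bad <- joined[is.na(joined$d_baseline) | is.na(joined$baseline_total), ]
    abort(
      paste0(
        "missing baseline pool or total for: ",
        paste(unique(paste(bad$crop, bad$outcome)), collapse = "; ")
      ),
      class = "nrimpact_missing_baseline"
    )
  }
  out <- joined |>
    dplyr::mutate(
      rejected = .data$k < min_k,
      effect_pct = ifelse(.data$rejected, NA_real_,
        strategy_effect_pct(.data$d_baseline, .data$d)),
      strategy_total = ifelse(.data$rejected, NA_real_,
        apply_strategy(.data$baseline_total, .data$effect_pct)),
      delta = .data$strategy_total - .data$baseline_total
    ) |>
    dplyr::select(
      "crop", "strategy", "outcome", "k", "d", "d_baseline",
      "effect_pct", "baseline_total", "strategy_total", "delta",
      "Q_p", "rejected"
    )
  class(out) <- c("nr_strategy_effects", class(out))
  out
}

#' Plot coupled strategy effects
#'
#' Bar chart of the change in each national total (delta vs baseline) per
#' strategy, facetted by crop and outcome; rejected groups are omitted.
#'
#' @param object An `nr_strategy_effects` tibble from [couple_strategies()].
#' @param ... Unused.
#' @export
autoplot.nr_strategy_effects <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !.data$rejected)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$strategy, y = .data$delta,
    fill = .data$delta < 0
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(.data$outcome ~ .data$crop, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "Change vs baseline (Tg; Gg for AEP)",
      title = "Coupled yield and environmental effects of mitigation strategies"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
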