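#' Pool baseline per-Mg potentials by crop and pathway
#'
#' Computes, for the baseline practice subset (urea, R2, surface, no
#' amendment), the random-effects pooled per-Mg potential of each crop x
#' pathway group — the absolute AP/GWP/AEP means in impact units per Mg
#' grains. By default each record enters as a single-group mean (its
#' treatment-arm yield-scaled potential, variance `sd^2/n`); the
#' `"difference"` mode pools treatment-minus-control contrasts instead.
#'
#' @param obs Imputed observation tibble ([impute_dispersions()]).
#' @param factors [equivalency_factors()].
#' @param mode `"single_group"` (default) or `"difference"`.
#' @param method Tau-squared estimator, `"DL"` or `"REML"`.
#' @param min_k Groups below this size are flagged `rejected`.
#' @return Tibble: `crop`, `pathway`, `impact`, `k`, `es_bar` (per-Mg
#'   potential), `se`, `ci_lb`, `ci_ub`, `tau2`, `Q`, `Q_p`, `I2`,
#'   `failsafe_n`, `rejected`.
#' @export
pool_baseline_impacts <- function(obs, factors = equivalency_factors(),
                                  mode = c("single_group", "difference"),
                                  method = "DL", min_k = 1) {
  mode <- match.arg(mode)
  base <- select_baseline(obs)
  with_es <- base |>
    add_impacts(factors = factors) |>
    compute_effect_sizes(
      value_treat = "impact_treat", value_ctrl = "impact_ctrl",
      sd_treat = "impact_sd_treat", sd_ctrl = "impact_sd_ctrl",
      mode = mode
    )
  with_es |>
    pool_groups(.data$crop, .data$pathway, .data$impact,
      method = method, min_k = min_k
    )
}

# single-group effect sizes for one outcome within an observation subset
outcome_effects <- function(df, outcome, factors, cv_yield) {
  if (outcome == "yield") {
    df$es <- df$yield_treat_mean
    df$v <- (cv_yield * df$yield_treat_mean)^2 / df$n_treat
    return(df[!is.na(df$v) & df$v > 0, , drop = FALSE])
  }
  pw <- c(AP = "NH3", GWP = "N2O", AEP = "NO3")[[outcome]]
  df <- dplyr::filter(df, .data$pathway == pw)
  if (nrow(df) == 0) return(df)
  df <- add_impacts(df, factors = factors)
  compute_effect_sizes(df,
    value_treat = "impact_treat", value_ctrl = "impact_ctrl",
    sd_treat = "impact_sd_treat", sd_ctrl = "impact_sd_ctrl",
    mode = "single_group"
  )
}

pool_outcomes_for_subset <- function(df, factors, cv_yield, method) {
  purrr::map_dfr(c("yield", "AP", "GWP", "AEP"), function(oc) {
    eff <- suppressWarnings(outcome_effects(df, oc, factors, cv_yield))
    if (nrow(eff) == 0) {
      return(tibble(outcome = oc, k = 0L, d = NA_real_, se = NA_real_,
        tau2 = NA_real_, Q_p = NA_real_))
    }
    p <- pool_effects(eff$es, eff$v, method = method)
    tibble(outcome = oc, k = p$k, d = p$es_bar, se = p$se,
      tau2 = p$tau2, Q_p = p$Q_p)
  })
}

#' Pooled outcomes under the baseline and every mitigation strategy
#'
#' For each crop, pools grain yield and the three per-Mg potentials within
#' the baseline subset and within each strategy subset
#' (see [select_strategy()]). Yield records carry no reported dispersion in
#' the schema, so their per-record variance is `(cv_yield * yield)^2 / n`.
#'
#' @inheritParams pool_baseline_impacts
#' @param cv_yield Assumed CV of reported yields, default 0.10.
#' @return List with `baseline` (crop, outcome, k, d, ...) and `strategies`
#'   (crop, strategy, outcome, k, d, ...).
#' @export
pool_strategy_outcomes <- function(obs, factors = equivalency_factors(),
                                   method = "DL", cv_yield = 0.10) {
  crops <- sort(unique(obs$crop))
  baseline <- purrr::map_dfr(crops, function(cr) {
    df <- select_baseline(dplyr::filter(obs, .data$crop == cr))
    pool_outcomes_for_subset(df, factors, cv_yield, method) |>
      dplyr::mutate(crop = cr, .before = 1)
  })
  strategies <- purrr::map_dfr(crops, function(cr) {
    purrr::map_dfr(strategy_levels(), function(st) {
      df <- select_strategy(dplyr::filter(obs, .data$crop == cr), st)
      pool_outcomes_for_subset(df, factors, cv_yield, method) |>
        dplyr::mutate(crop = cr, strategy = st, .before = 1)
    })
  })
  list(baseline = baseline, strategies = strategies)
}

#' End-to-end strategy coupling for an observation database
#'
#' Chains the full coupling computation: pools baseline and strategy
#' outcomes, upscales the baseline per-Mg potentials to national totals
#' over the provincial yields, and expresses each strategy as percent and
#' absolute changes against those totals.
#'
#' @inheritParams pool_strategy_outcomes
#' @param yields Provincial yields tibble (`province`, `crop`,
#'   `production_Mg`).
#' @param min_k Minimum comparisons per strategy group, default 3.
#' @return A [couple_strategies()] result.
#' @export
analyse_strategy_coupling <- function(obs, yields, factors = equivalency_factors(),
                                      method = "DL", cv_yield = 0.10, min_k = 3) {
  pools <- pool_strategy_outcomes(obs, factors, method, cv_yield)
  totals <- purrr::map_dfr(sort(unique(pools$baseline$crop)), function(cr) {
    bp <- pools$baseline[pools$baseline$crop == cr, ]
    per_mg <- setNames(bp$d[match(c("AP", "GWP", "AEP"), bp$outcome)],
      c("ap", "gwp", "aep"))
    per_mg <- per_mg[!is.na(per_mg)]
    yl <- dplyr::filter(yields, .data$crop == cr)
    nt <- national_total(per_mg, yl)
    tibble(
      crop = cr,
      outcome = c("yield", "AP", "GWP", "AEP"),
      total = c(nt$production_total_Tg, nt$ap_total_Tg,
        nt$gwp_total_Tg, nt$aep_total_Gg)
    )
  })
  couple_strategies(
    pools$strategies, pools$baseline, totals,
    min_k = min_k
  )
}

#' Driver importance per crop and impact
#'
#' Runs the all-subsets AICc selection on the baseline subset of each
#' crop x pathway group, using the single-group per-Mg potentials as effect
#' sizes and the six environmental moderators as candidate drivers.
#'
#' @inheritParams pool_baseline_impacts
#' @param drivers Candidate moderator columns.
#' @param cutoff Importance cutoff, default 0.8.
#' @return Tibble with one row per crop x impact: `crop`, `impact`, the
#'   `nr_importance` object in list-column `selection`, plus the unnested
#'   importance table in `importance`.
#' @export
analyse_drivers <- function(obs, factors = equivalency_factors(),
                            drivers = .moderator_names, cutoff = 0.8,
                            method = "DL") {
  base <- select_baseline(obs)
  grid <- dplyr::distinct(base, .data$crop, .data$pathway)
  purrr::pmap_dfr(grid, function(crop, pathway) {
    df <- dplyr::filter(base, .data$crop == !!crop, .data$pathway == !!pathway)
    eff <- suppressWarnings(
      add_impacts(df, factors = factors) |>
        compute_effect_sizes(
          value_treat = "impact_treat", value_ctrl = "impact_ctrl",
          sd_treat = "impact_sd_treat", sd_ctrl = "impact_sd_ctrl",
          mode = "single_group"
        )
    )
    sel <- tryCatch(
      all_subsets_selection(eff$es, eff$v, eff[drivers],
        drivers = drivers, cutoff = cutoff, method = method
      ),
      nrimpact_insufficient_studies = function(e) NULL
    )
    tibble(
      crop = crop,
      impact = c(NH3 = "AP", N2O = "GWP", NO3 = "AEP")[[pathway]],
      k = nrow(eff),
      selection = list(sel),
      importance = list(if (is.null(sel)) NULL else sel$importance)
    )
  })
}
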