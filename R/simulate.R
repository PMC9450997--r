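#' Simulation configuration for synthetic observation databases
#'
#' Bundles every parameter of the synthetic generator. Defaults emulate the
#' structure of the field-observation database the analysis is designed for:
#' 1,893 pairwise datasets split 60/21/19% across the NH3/N2O/NO3 pathways,
#' equal crop shares, a baseline practice (urea, conventional rate, surface,
#' no amendment) holding 40% of each crop-pathway cell with the remainder
#' spread over nine mitigation strategies, true per-Mg potentials equal to
#' the pooled values the analysis is expected to recover (AP 131/109/153
#' acid equiv., GWP 74/33/35 kg CO2 equiv., AEP 0.37/0.34/0.03 kg PO4
#' equiv. for wheat/maize/rice), between-study SD at 15% of the group mean,
#' within-replicate CV 20%, 3-4 replicates, 30% of records missing a
#' reported SD, and moderators drawn from realistic seasonal ranges
#' (temperature 7-24 degC, water load 20-2000 mm).
#'
#' @param seed Integer seed (mandatory; the generator is fully
#'   deterministic given the seed).
#' @param n_total Total number of pairwise datasets.
#' @param pathway_shares,crop_shares Named shares summing to 1.
#' @param baseline_share Share of each crop-pathway cell assigned to the
#'   baseline practice.
#' @param true_per_mg Tibble (`crop`, `pathway`, `per_mg`) of true baseline
#'   per-Mg potentials in impact units; converted internally to yield-scaled
#'   N losses through `factors`.
#' @param factors [equivalency_factors()] used for that conversion.
#' @param rel_tau Between-study SD as a fraction of the group mean.
#' @param within_cv Within-replicate CV of seasonal losses.
#' @param rep_counts Integer vector replicate counts are drawn from.
#' @param yield_mean Named mean grain yields, Mg ha^-1.
#' @param yield_cv CV of study-level yields.
#' @param ctrl_yield_frac Control (zero-N) yield as a fraction of treatment.
#' @param ctrl_loss_frac Control background loss as a fraction of treatment.
#' @param conventional_rate_mean Named mean conventional N rates, kg N ha^-1.
#' @param moderator_ranges Named list of `c(min, max)` uniform ranges.
#' @param moderator_slopes Named additive effects on the yield-scaled loss
#'   per one population SD of the moderator (default all zero).
#' @param missing_dispersion_rate Probability a record's SD is masked.
#' @param missing_kinds Named probabilities of the replacement dispersion
#'   kind used when masking.
#' @param strategy_true_effects Tibble (`strategy`, `loss_pct`,
#'   `yield_pct`): true percent decreases below baseline (positive =
#'   decrease) for yield-scaled losses and yields.
#' @param national_production_Mg Named national grain production targets, Mg.
#' @param n_provinces Number of provinces for the yields table.
#' @return A list of class `nr_sim_config`.
#' @export
sim_config <- function(seed,
                       n_total = 1893,
                       pathway_shares = c(NH3 = 0.60, N2O = 0.21, NO3 = 0.19),
                       crop_shares = c(wheat = 1 / 3, maize = 1 / 3, rice = 1 / 3),
                       baseline_share = 0.40,
                       true_per_mg = default_true_per_mg(),
                       factors = equivalency_factors(),
                       rel_tau = 0.15,
                       within_cv = 0.20,
                       rep_counts = 3:4,
                       yield_mean = c(wheat = 6, maize = 7, rice = 7),
                       yield_cv = 0.10,
                       ctrl_yield_frac = 0.6,
                       ctrl_loss_frac = 0.1,
                       conventional_rate_mean = c(wheat = 200, maize = 230, rice = 215),
                       moderator_ranges = list(
                         temperature = c(7, 24), water_load = c(20, 2000),
                         soil_ph = c(5, 8.5), som = c(5, 40),
                         stn = c(0.5, 2.5), clay = c(100, 500)
                       ),
                       moderator_slopes = c(
                         temperature = 0, water_load = 0, soil_ph = 0,
                         som = 0, stn = 0, clay = 0
                       ),
                       missing_dispersion_rate = 0.30,
                       missing_kinds = c(
                         SE = 0.30, CV = 0.25, CI = 0.15,
                         t_value = 0.10, p_value = 0.05, missing = 0.15
                       ),
                       strategy_true_effects = default_strategy_effects(),
                       national_production_Mg = c(
                         wheat = 131.4e6, maize = 257.2e6, rice = 212.1e6
                       ),
                       n_provinces = 31) {
  if (missing(seed) || !is.numeric(seed) || is.na(seed)) {
    abort("seed is mandatory in a simulation config", class = "nrimpact_config_error")
  }
  stopifnot(
    abs(sum(pathway_shares) - 1) < 1e-8, abs(sum(crop_shares) - 1) < 1e-8,
    baseline_share > 0, baseline_share < 1
  )
  if (rel_tau < 0 || within_cv < 0 || missing_dispersion_rate < 0 ||
    missing_dispersion_rate > 1) {
    abort("variances must be >= 0 and probabilities in [0, 1]",
      class = "nrimpact_config_error"
    )
  }
  cfg <- list(
    seed = as.integer(seed), n_total = n_total,
    pathway_shares = pathway_shares, crop_shares = crop_shares,
    baseline_share = baseline_share, true_per_mg = true_per_mg,
    factors = factors, rel_tau = rel_tau, within_cv = within_cv,
    rep_counts = rep_counts, yield_mean = yield_mean, yield_cv = yield_cv,
    ctrl_yield_frac = ctrl_yield_frac, ctrl_loss_frac = ctrl_loss_frac,
    conventional_rate_mean = conventional_rate_mean,
    moderator_ranges = moderator_ranges, moderator_slopes = moderator_slopes,
    missing_dispersion_rate = missing_dispersion_rate,
    missing_kinds = missing_kinds / sum(missing_kinds),
    strategy_true_effects = strategy_true_effects,
    national_production_Mg = national_production_Mg,
    n_provinces = n_provinces
  )
  class(cfg) <- "nr_sim_config"
  cfg
}

#' Default true baseline per-Mg potentials
#'
#' @return Tibble (`crop`, `pathway`, `per_mg`) in impact units per Mg
#'   grains (acid equiv. for NH3, kg CO2 equiv. for N2O, kg PO4 equiv. for
#'   NO3).
#' @export
default_true_per_mg <- function() {
  tibble(
    crop = rep(c("wheat", "maize", "rice"), each = 3),
    pathway = rep(c("NH3", "N2O", "NO3"), times = 3),
    per_mg = c(131, 74, 0.37, 109, 33, 0.34, 153, 35, 0.03)
  )
}

#' Default true strategy effects
#'
#' Percent decreases below baseline (positive = decrease) in yield-scaled
#' losses and yields for each mitigation strategy; plausible magnitudes for
#' the lever each strategy pulls (rate reduction cuts losses and yield,
#' excessive rates raise both, inhibitors and subsurface placement cut
#' losses while raising yield, etc.).
#'
#' @return Tibble (`strategy`, `loss_pct`, `yield_pct`).
#' @export
default_strategy_effects <- function() {
  tibble(
    strategy = strategy_levels(),
    loss_pct = c(25, -20, 10, 30, 15, 20, 10, 15, 35),
    yield_pct = c(15, -8, 8, 5, 5, -5, -10, -2, -8)
  )
}

.province_names <- paste0("P", sprintf("%02d", 1:31))

# allocate n across shares so the total is exact (largest remainder)
largest_remainder <- function(n, shares) {
  raw <- n * shares / sum(shares)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic observation database with known ground truth
#'
#' Draws, for every crop x pathway x practice group, study-level true
#' yield-scaled losses from `Normal(group mean, tau^2)`, converts them to
#' per-hectare seasonal losses through study yields, emits replicate-level
#' SDs, then masks a configured share of the dispersions using exact inverse
#' transforms (SE = SD/sqrt(n), CV = 100 SD/mean, CI half-width from the t
#' quantile, t and p from the comparison) or removes them entirely so the
#' bootstrap imputation route is exercised. Moderators are drawn uniformly
#' from their configured ranges and any configured slopes act on the
#' yield-scaled loss. The same seed yields byte-identical output.
#'
#' @param config A [sim_config()].
#' @return List of class `nr_simulation`: `observations` (schema-valid
#'   tibble), `truth` (per-group true means and tau2, true per-Mg
#'   potentials, strategy effects, moderator slopes, national totals) and
#'   the `config`.
#' @export
simulate_observations <- function(config) {
  stopifnot(inherits(config, "nr_sim_config"))
  cfg <- config
  crops <- names(cfg$crop_shares)
  pathways <- names(cfg$pathway_shares)
  strategies <- cfg$strategy_true_effects$strategy

  # true yield-scaled N loss per crop x pathway (baseline)
  fac <- c(
    NH3 = cfg$factors$ap_per_kg_nh3n,
    N2O = cfg$factors$gwp_per_kg_n2on,
    NO3 = cfg$factors$aep_per_kg_no3n
  )
  base_truth <- cfg$true_per_mg |>
    dplyr::mutate(mu_scaled = .data$per_mg / as.numeric(fac[.data$pathway]))

  # group allocation
  cells <- tidyr::expand_grid(crop = crops, pathway = pathways)
  n_crop <- largest_remainder(cfg$n_total, cfg$crop_shares[cells$crop[!duplicated(cells$crop)]])
  alloc <- list()
  for (ci in seq_along(crops)) {
    n_pw <- largest_remainder(n_crop[ci], cfg$pathway_shares)
    for (pi in seq_along(pathways)) {
      n_cell <- n_pw[pi]
      n_base <- max(2L, as.integer(round(n_cell * cfg$baseline_share)))
      n_strat <- largest_remainder(n_cell - n_base, rep(1, length(strategies)))
      alloc[[length(alloc) + 1]] <- tibble(
        crop = crops[ci], pathway = pathways[pi],
        strategy = c("baseline", strategies),
        n = c(n_base, n_strat)
      )
    }
  }
  groups <- dplyr::bind_rows(alloc) |>
    dplyr::left_join(base_truth, by = c("crop", "pathway")) |>
    dplyr::left_join(cfg$strategy_true_effects, by = "strategy") |>
    dplyr::mutate(
      loss_pct = dplyr::coalesce(.data$loss_pct, 0),
      yield_pct = dplyr::coalesce(.data$yield_pct, 0),
      mu_group = .data$mu_scaled * (1 - .data$loss_pct / 100),
      tau = cfg$rel_tau * .data$mu_group
    )

  obs <- with_preserved_seed(cfg$seed, {
    rows <- purrr::pmap_dfr(groups, function(crop, pathway, strategy, n, per_mg,
                                             mu_scaled, loss_pct, yield_pct,
                                             mu_group, tau) {
      if (n == 0) return(NULL)
      theta <- rnorm(n, mu_group, tau)
      # moderators and their planted effects on the scaled loss
      mods <- purrr::imap_dfc(cfg$moderator_ranges, function(rg, nm) {
        tibble(!!nm := runif(n, rg[1], rg[2]))
      })
      for (nm in names(cfg$moderator_slopes)) {
        sl <- cfg$moderator_slopes[[nm]]
        if (sl != 0) {
          rg <- cfg$moderator_ranges[[nm]]
          z <- (mods[[nm]] - mean(rg)) / (diff(rg) / sqrt(12))
          theta <- theta + sl * z
        }
      }
      theta <- pmax(theta, 0.02 * mu_group)
      ymu <- cfg$yield_mean[[crop]] * (1 - yield_pct / 100)
      yield_t <- pmax(rnorm(n, ymu, cfg$yield_cv * ymu), 0.5)
      yield_c <- cfg$ctrl_yield_frac * yield_t
      n_t <- if (length(cfg$rep_counts) == 1) rep(cfg$rep_counts, n) else
        sample(cfg$rep_counts, n, replace = TRUE)
      n_c <- if (length(cfg$rep_counts) == 1) rep(cfg$rep_counts, n) else
        sample(cfg$rep_counts, n, replace = TRUE)
      # replicate-noise scale is set by the group mean, not the study draw,
      # so inverse-variance weights stay uncorrelated with the effect sizes
      sd_t <- cfg$within_cv * mu_group * yield_t
      sd_c <- cfg$within_cv * cfg$ctrl_loss_frac * mu_group * yield_t
      loss_t <- pmax(theta * yield_t + rnorm(n, 0, sd_t / sqrt(n_t)), 1e-6)
      loss_c <- pmax(cfg$ctrl_loss_frac * theta * yield_t +
        rnorm(n, 0, sd_c / sqrt(n_c)), 1e-6)
      n_rate <- switch(strategy,
        R1 = runif(n, 60, 149),
        R3 = runif(n, 250, 350),
        pmin(pmax(rnorm(n, cfg$conventional_rate_mean[[crop]], 20), 150), 249)
      )
      tibble(
        study_id = NA_character_, site_id = NA_character_,
        province = sample(.province_names[seq_len(cfg$n_provinces)], n, replace = TRUE),
        crop = crop, pathway = pathway,
        n_source = switch(strategy, OCF = "OCF", IU = "IU", OA = "OA", "urea"),
        n_rate = n_rate,
        placement = if (strategy == "subsurface") "subsurface" else "surface",
        amendment = if (strategy %in% c("mulch", "biochar", "inhibitor")) strategy else "none",
        loss_treat_mean = loss_t, loss_ctrl_mean = loss_c,
        yield_treat_mean = yield_t, yield_ctrl_mean = yield_c,
        n_treat = n_t, n_ctrl = n_c,
        sd_true_treat = sd_t, sd_true_ctrl = sd_c
      ) |> dplyr::bind_cols(mods)
    })
    rows$study_id <- sprintf("study_%04d", seq_len(nrow(rows)))
    rows$site_id <- sprintf("site_%04d", seq_len(nrow(rows)))

    # emit dispersions: reported SD by default, masked kinds for a share
    n_all <- nrow(rows)
    masked <- runif(n_all) < cfg$missing_dispersion_rate
    kind <- rep("SD", n_all)
    kind[masked] <- sample(names(cfg$missing_kinds), sum(masked),
      replace = TRUE, prob = cfg$missing_kinds
    )
    blank <- function(n) rep(NA_real_, n)
    d <- tibble(
      disp_treat_kind = kind, disp_treat_value = blank(n_all),
      disp_treat_lower = blank(n_all), disp_treat_upper = blank(n_all),
      disp_treat_level = blank(n_all),
      disp_ctrl_kind = kind, disp_ctrl_value = blank(n_all),
      disp_ctrl_lower = blank(n_all), disp_ctrl_upper = blank(n_all),
      disp_ctrl_level = blank(n_all)
    )
    md <- rows$loss_treat_mean - rows$loss_ctrl_mean
    sp <- sqrt(((rows$n_treat - 1) * rows$sd_true_treat^2 +
      (rows$n_ctrl - 1) * rows$sd_true_ctrl^2) / (rows$n_treat + rows$n_ctrl - 2))
    se_d <- sp * sqrt((rows$n_treat + rows$n_ctrl) / (rows$n_treat * rows$n_ctrl))
    tval <- md / se_d
    for (i in seq_len(n_all)) {
      kt <- kind[i]
      st <- rows$sd_true_treat[i]
      sc <- rows$sd_true_ctrl[i]
      if (kt == "SD") {
        d$disp_treat_value[i] <- st
        d$disp_ctrl_value[i] <- sc
      } else if (kt == "SE") {
        d$disp_treat_value[i] <- st / sqrt(rows$n_treat[i])
        d$disp_ctrl_value[i] <- sc / sqrt(rows$n_ctrl[i])
      } else if (kt == "CV") {
        d$disp_treat_value[i] <- 100 * st / rows$loss_treat_mean[i]
        d$disp_ctrl_value[i] <- 100 * sc / rows$loss_ctrl_mean[i]
      } else if (kt == "CI") {
        hw_t <- qt(0.975, rows$n_treat[i] - 1) * st / sqrt(rows$n_treat[i])
        hw_c <- qt(0.975, rows$n_ctrl[i] - 1) * sc / sqrt(rows$n_ctrl[i])
        d$disp_treat_lower[i] <- rows$loss_treat_mean[i] - hw_t
        d$disp_treat_upper[i] <- rows$loss_treat_mean[i] + hw_t
        d$disp_treat_level[i] <- 0.95
        d$disp_ctrl_lower[i] <- rows$loss_ctrl_mean[i] - hw_c
        d$disp_ctrl_upper[i] <- rows$loss_ctrl_mean[i] + hw_c
        d$disp_ctrl_level[i] <- 0.95
      } else if (kt == "t_value") {
        d$disp_treat_value[i] <- tval[i]
        d$disp_ctrl_kind[i] <- "missing"
      } else if (kt == "p_value") {
        df_i <- rows$n_treat[i] + rows$n_ctrl[i] - 2
        p_i <- min(max(2 * pt(-abs(tval[i]), df_i), 1e-12), 1 - 1e-12)
        d$disp_treat_value[i] <- p_i
        d$disp_ctrl_kind[i] <- "missing"
      }
    }
    dplyr::bind_cols(
      dplyr::select(rows, -"sd_true_treat", -"sd_true_ctrl"), d
    ) |>
      dplyr::mutate(
        sd_true_treat = rows$sd_true_treat,
        sd_true_ctrl = rows$sd_true_ctrl
      )
  })

  # reorder columns to the schema, keep truth columns at the end
  sch_cols <- observation_schema()$columns$name
  obs <- obs[c(sch_cols, setdiff(names(obs), sch_cols))]

  base_per_mg <- base_truth |>
    dplyr::mutate(impact = dplyr::case_match(.data$pathway,
      "NH3" ~ "AP", "N2O" ~ "GWP", "NO3" ~ "AEP"))
  nt <- purrr::map_dfr(crops, function(cr) {
    pm <- base_per_mg[base_per_mg$crop == cr, ]
    national_total(
      setNames(pm$per_mg, tolower(pm$impact)),
      tibble(province = "CHN", crop = cr,
        production_Mg = cfg$national_production_Mg[[cr]])
    )
  })

  truth <- list(
    groups = dplyr::select(groups, "crop", "pathway", "strategy", "n",
      "per_mg", "mu_group", "tau", "loss_pct", "yield_pct") |>
      dplyr::mutate(tau2 = .data$tau^2),
    true_per_mg = base_per_mg,
    strategy_effects = cfg$strategy_true_effects,
    moderator_slopes = cfg$moderator_slopes,
    national_totals = nt
  )
  structure(
    list(observations = obs, truth = truth, config = cfg),
    class = "nr_simulation"
  )
}

#' @export
print.nr_simulation <- function(x, ...) {
  cat("Synthetic observation database:", nrow(x$observations), "pairwise records\n")
  cat("  seed:", x$config$seed, "\n")
  print(dplyr::count(x$observations, .data$crop, .data$pathway))
  invisible(x)
}

#' Generate a provincial grain-yield table
#'
#' Allocates each crop's national production over provinces with random
#' weights, rounding to whole megagrams by the largest-remainder rule so the
#' provincial productions sum exactly to the target.
#'
#' @param config A [sim_config()]; `national_production_Mg` and
#'   `n_provinces` are used.
#' @return Tibble (`province`, `crop`, `production_Mg`) with
#'   `sum(production_Mg) == target` exactly per crop.
#' @export
simulate_province_yields <- function(config) {
  stopifnot(inherits(config, "nr_sim_config"))
  with_preserved_seed(config$seed + 1L, {
    purrr::map_dfr(names(config$national_production_Mg), function(cr) {
      target <- round(config$national_production_Mg[[cr]])
      if (target < 0) abort("production target must be >= 0", class = "nrimpact_config_error")
      w <- rgamma(config$n_provinces, shape = 2)
      tibble(
        province = .province_names[seq_len(config$n_provinces)],
        crop = cr,
        production_Mg = as.numeric(largest_remainder(target, w))
      )
    })
  })
}
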