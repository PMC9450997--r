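#' Life-cycle equivalency factors
#'
#' Pathway-specific conversion constants from yield-scaled Nr losses
#' (kg N Mg^-1 grains) into environmental potentials: acidification
#' (58.75 acid equiv. per kg NH3-N), global warming (298 kg CO2 equiv. per
#' kg N2O-N, the 100-year horizon) and aquatic eutrophication (0.1 kg PO4
#' equiv. per kg NO3-N). Defaults are locked to these constants; overrides
#' exist for sensitivity analyses with alternative characterization factors.
#'
#' @param ap_per_kg_nh3n Acid equiv. per kg NH3-N, default 58.75.
#' @param gwp_per_kg_n2on kg CO2 equiv. per kg N2O-N, default 298.
#' @param aep_per_kg_no3n kg PO4 equiv. per kg NO3-N, default 0.1.
#' @return Named list of class `nr_factors`.
#' @export
equivalency_factors <- function(ap_per_kg_nh3n = 58.75,
                                gwp_per_kg_n2on = 298,
                                aep_per_kg_no3n = 0.1) {
  f <- list(
    ap_per_kg_nh3n = ap_per_kg_nh3n,
    gwp_per_kg_n2on = gwp_per_kg_n2on,
    aep_per_kg_no3n = aep_per_kg_no3n
  )
  if (any(vapply(f, function(x) !is.numeric(x) || is.na(x) || x <= 0, logical(1)))) {
    abort("equivalency factors must be strictly positive numbers",
      class = "nrimpact_config_error"
    )
  }
  structure(f, class = "nr_factors")
}

#' Yield-scale a seasonal Nr loss
#'
#' Divides a seasonal loss (kg N ha^-1) by grain yield (Mg ha^-1) to express
#' the environmental burden per unit of food produced (kg N Mg^-1 grains).
#'
#' @param loss Seasonal Nr loss, kg N ha^-1, >= 0.
#' @param gy Grain yield, Mg ha^-1, > 0.
#' @return `loss / gy`, kg N Mg^-1.
#' @export
yield_scale <- function(loss, gy) {
  if (any(is.na(loss)) || any(loss < 0)) {
    abort("loss must be >= 0", class = "nrimpact_domain_error")
  }
  if (any(is.na(gy)) || any(gy <= 0)) {
    abort("grain yield must be > 0 to yield-scale", class = "nrimpact_domain_error")
  }
  loss / gy
}

#' Convert a yield-scaled loss into its environmental potential
#'
#' Applies the pathway's equivalency factor: NH3 losses map to acidification
#' potential, N2O to global-warming potential, NO3 to aquatic-eutrophication
#' potential. The two impact columns not matching the pathway are `NA`.
#'
#' @param scaled_loss Yield-scaled Nr-N loss, kg N Mg^-1 grains, >= 0. When
#'   a dataset reports the N2O molecule rather than N2O-N, convert first
#'   (`as_n2o_molecule = TRUE` multiplies by 28/44).
#' @param pathway Character vector over `"NH3"`, `"N2O"`, `"NO3"` (recycled
#'   against `scaled_loss`).
#' @param factors An [equivalency_factors()] object.
#' @param as_n2o_molecule Interpret N2O inputs as kg N2O instead of
#'   kg N2O-N; default `FALSE`.
#' @return Tibble with columns `pathway`, `yield_scaled_loss`, `ap`, `gwp`,
#'   `aep` (exactly one impact non-`NA` per row).
#' @examples
#' to_impact(1, "NH3")
#' @export
to_impact <- function(scaled_loss, pathway, factors = equivalency_factors(),
                      as_n2o_molecule = FALSE) {
  if (any(is.na(scaled_loss)) || any(scaled_loss < 0)) {
    abort("scaled_loss must be >= 0", class = "nrimpact_domain_error")
  }
  n <- max(length(scaled_loss), length(pathway))
  scaled_loss <- rep_len(scaled_loss, n)
  pathway <- rep_len(pathway, n)
  if (!all(pathway %in% .pathway_levels)) {
    abort("pathway must be one of NH3, N2O, NO3", class = "nrimpact_domain_error")
  }
  x <- scaled_loss
  is_n2o <- pathway == "N2O"
  if (as_n2o_molecule) x[is_n2o] <- x[is_n2o] * 28 / 44
  tibble(
    pathway = pathway,
    yield_scaled_loss = x,
    ap = ifelse(pathway == "NH3", x * factors$ap_per_kg_nh3n, NA_real_),
    gwp = ifelse(is_n2o, x * factors$gwp_per_kg_n2on, NA_real_),
    aep = ifelse(pathway == "NO3", x * factors$aep_per_kg_no3n, NA_real_)
  )
}

#' Augment an observation table with yield-scaled losses and impacts
#'
#' Adds, for both arms, the yield-scaled loss and the pathway-matched
#' potential (`ap` / `gwp` / `aep`) plus the yield-scaled outcome SDs needed
#' for effect-size variances (`sd / yield`, scaled by the same factor).
#'
#' @param obs Imputed observation tibble (see [impute_dispersions()]).
#' @param factors An [equivalency_factors()] object.
#' @param as_n2o_molecule See [to_impact()].
#' @return `obs` with columns `scaled_loss_treat`, `scaled_loss_ctrl`,
#'   `impact_treat`, `impact_ctrl`, `impact_sd_treat`, `impact_sd_ctrl`,
#'   `impact` (which potential the row carries).
#' @export
add_impacts <- function(obs, factors = equivalency_factors(),
                        as_n2o_molecule = FALSE) {
  fac <- dplyr::case_match(obs$pathway,
    "NH3" ~ factors$ap_per_kg_nh3n,
    "N2O" ~ factors$gwp_per_kg_n2on,
    "NO3" ~ factors$aep_per_kg_no3n
  )
  mol <- ifelse(as_n2o_molecule & obs$pathway == "N2O", 28 / 44, 1)
  out <- obs
  out$impact <- dplyr::case_match(obs$pathway,
    "NH3" ~ "AP", "N2O" ~ "GWP", "NO3" ~ "AEP"
  )
  out$scaled_loss_treat <- yield_scale(obs$loss_treat_mean, obs$yield_treat_mean) * mol
  out$scaled_loss_ctrl <- yield_scale(obs$loss_ctrl_mean, obs$yield_ctrl_mean) * mol
  out$impact_treat <- out$scaled_loss_treat * fac
  out$impact_ctrl <- out$scaled_loss_ctrl * fac
  if (!is.null(obs$sd_treat)) {
    out$impact_sd_treat <- obs$sd_treat / obs$yield_treat_mean * mol * fac
    out$impact_sd_ctrl <- obs$sd_ctrl / obs$yield_ctrl_mean * mol * fac
  }
  out
}
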