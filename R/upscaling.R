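#' Read a provincial grain-yield table
#'
#' @param path CSV with columns `province`, `crop`, `production_Mg`.
#' @return Validated tibble.
#' @export
read_province_yields <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("yields file not found: ", path), class = "nrimpact_io_error")
  }
  df <- readr::read_csv(path,
    col_types = readr::cols(
      province = readr::col_character(),
      crop = readr::col_character(),
      production_Mg = readr::col_double()
    ), progress = FALSE
  )
  df$crop <- normalize_enum(df$crop, .crop_levels)
  validate_province_yields(df)
  df
}

validate_province_yields <- function(yields) {
  need <- c("province", "crop", "production_Mg")
  miss <- setdiff(need, names(yields))
  if (length(miss) > 0) {
    abort(paste0("yields table is missing column(s): ", paste(miss, collapse = ", ")),
      class = "nrimpact_schema_error"
    )
  }
  if (any(is.na(yields$crop)) || !all(yields$crop %in% .crop_levels)) {
    abort("yields crop must be one of wheat/maize/rice", class = "nrimpact_domain_error")
  }
  if (any(is.na(yields$production_Mg)) || any(yields$production_Mg < 0)) {
    abort("production_Mg must be >= 0", class = "nrimpact_domain_error")
  }
  counts <- table(yields$crop)
  if (any(counts > 31)) {
    abort("at most 31 provinces per crop", class = "nrimpact_domain_error")
  }
  invisible(yields)
}

#' National impact totals from per-Mg burdens
#'
#' Scales pooled per-megagram potentials to national totals by summing
#' `per_mg x production` over provinces, dividing by 1e9 to express AP and
#' GWP in Tg and by 1e6 to express AEP in Gg:
#' \deqn{AP_{total} = \sum_i AP_i \, GY_i / 10^9 \quad (Tg), \qquad
#'  AEP_{total} = \sum_i AEP_i \, GY_i / 10^6 \quad (Gg).}
#' Totals are linear in production, so any provincial partitioning of the
#' same national production gives identical totals; a single pseudo-province
#' row carrying national production is acceptable.
#'
#' @param per_mg Named numeric with any of `ap` (acid equiv. Mg^-1), `gwp`
#'   (kg CO2 equiv. Mg^-1), `aep` (kg PO4 equiv. Mg^-1); all >= 0.
#' @param yields Provincial yields tibble (`province`, `crop`,
#'   `production_Mg`) for a single crop.
#' @return One-row tibble: `crop`, `production_total_Tg`, `ap_total_Tg`,
#'   `gwp_total_Tg`, `aep_total_Gg`.
#' @examples
#' national_total(
#'   c(aep = 0.37),
#'   tibble::tibble(province = "CHN", crop = "wheat", production_Mg = 131.4e6)
#' )
#' @export
national_total <- function(per_mg, yields) {
  validate_province_yields(yields)
  if (nrow(yields) == 0) {
    abort("yields table is empty", class = "nrimpact_empty_group")
  }
  if (length(unique(yields$crop)) > 1) {
    abort("national_total takes a single crop per call; split the table first",
      class = "nrimpact_domain_error"
    )
  }
  known <- c("ap", "gwp", "aep")
  if (is.null(names(per_mg)) || !all(names(per_mg) %in% known)) {
    abort("per_mg must be named over ap/gwp/aep", class = "nrimpact_domain_error")
  }
  if (any(is.na(per_mg)) || any(per_mg < 0)) {
    abort("per_mg values must be >= 0", class = "nrimpact_domain_error")
  }
  gy <- sum(yields$production_Mg)
  get <- function(nm) if (nm %in% names(per_mg)) unname(per_mg[[nm]]) else NA_real_
  tibble(
    crop = yields$crop[1],
    production_total_Tg = gy / 1e6, # 1 Tg = 1e6 Mg
    ap_total_Tg = get("ap") * gy / 1e9,
    gwp_total_Tg = get("gwp") * gy / 1e9,
    aep_total_Gg = get("aep") * gy / 1e6
  )
}
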