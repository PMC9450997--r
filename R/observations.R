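#' Observation table schema
#'
#' The machine-readable column schema shipped with the package. One descriptor
#' file exists per schema version under `inst/extdata/`.
#'
#' @param version Schema version string, currently only `"v1"`.
#' @return A list with the schema metadata and a `columns` tibble
#'   (name, type, required, levels).
#' @export
observation_schema <- function(version = "v1") {
  path <- system.file("extdata",
    paste0("observations_schema_", version, ".json"),
    package = "nrimpact"
  )
  if (path == "") {
    abort(paste0("unknown observation schema version: ", version),
      class = "nrimpact_schema_error"
    )
  }
  sch <- jsonlite::read_json(path, simplifyVector = FALSE)
  cols <- purrr::map_dfr(sch$columns, function(col) {
    tibble(
      name = col$name,
      type = col$type,
      required = isTRUE(col$required),
      levels = list(as.character(unlist(col$levels %||% character())))
    )
  })
  list(
    version = sch$version,
    columns = cols,
    units = sch$units,
    conventional_rate_ranges = sch$conventional_rate_ranges_kgN_ha
  )
}

# canonical enum levels
.crop_levels <- c("wheat", "maize", "rice")
.pathway_levels <- c("NH3", "N2O", "NO3")
.n_source_levels <- c("urea", "OCF", "IU", "OA")
.placement_levels <- c("surface", "subsurface")
.amendment_levels <- c("none", "mulch", "biochar", "inhibitor")
.dispersion_kinds <- c("SD", "SE", "CV", "CI", "t_value", "p_value", "missing")
.moderator_names <- c("temperature", "water_load", "soil_ph", "som", "stn", "clay")

# case-insensitive normalization of an enum column; unmatched values become NA
normalize_enum <- function(x, levels) {
  idx <- match(tolower(trimws(as.character(x))), tolower(levels))
  levels[idx]
}

#' Read an observation table
#'
#' Reads the pairwise treatment/control observation CSV (one row per
#' comparison: seasonal Nr loss means, grain yields, replicate counts,
#' reported dispersions, management descriptors and environmental
#' moderators), normalizes enum columns case-insensitively and validates
#' every row against the schema invariants. Units are taken as documented in
#' the schema (losses kg N ha^-1 season^-1, yields Mg ha^-1, rates
#' kg N ha^-1); no unit conversion happens at read time, and reported
#' dispersions are preserved untransformed.
#'
#' @param path Path to a CSV file.
#' @param schema_version Schema version the file claims to follow.
#' @param on_invalid `"error"` (default) aborts naming the offending rows;
#'   `"drop"` rejects invalid rows with a warning and attaches the
#'   row-indexed diagnostics as attribute `"diagnostics"`.
#' @return A tibble of observations, one row per pairwise comparison.
#' @seealso [write_observations()], [validate_observations()]
#' @export
read_observations <- function(path, schema_version = "v1",
                              on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) {
    abort(paste0("observation file not found: ", path),
      class = "nrimpact_io_error"
    )
  }
  sch <- observation_schema(schema_version)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- sch$columns$name[sch$columns$required]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "observation file is missing mandatory column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "nrimpact_schema_error"
    )
  }
  # add optional columns absent from the file
  for (nm in setdiff(sch$columns$name, names(raw))) raw[[nm]] <- NA_character_
  raw <- raw[sch$columns$name]

  num_cols <- sch$columns$name[sch$columns$type %in% c("numeric", "integer")]
  obs <- raw
  for (nm in num_cols) obs[[nm]] <- suppressWarnings(as.numeric(raw[[nm]]))
  obs$n_treat <- as.integer(obs$n_treat)
  obs$n_ctrl <- as.integer(obs$n_ctrl)
  obs$crop <- normalize_enum(raw$crop, .crop_levels)
  obs$pathway <- normalize_enum(raw$pathway, .pathway_levels)
  obs$n_source <- normalize_enum(raw$n_source, .n_source_levels)
  obs$placement <- normalize_enum(raw$placement, .placement_levels)
  obs$amendment <- normalize_enum(raw$amendment, .amendment_levels)
  obs$disp_treat_kind <- normalize_enum(raw$disp_treat_kind, .dispersion_kinds)
  obs$disp_ctrl_kind <- normalize_enum(raw$disp_ctrl_kind, .dispersion_kinds)
  obs <- as_tibble(obs)

  diag <- validate_observations(obs)
  if (nrow(diag) > 0) {
    if (on_invalid == "error") {
      msgs <- head(paste0("row ", diag$row, ": ", diag$message), 10)
      abort(
        c("invalid observation rows:", setNames(msgs, rep("x", length(msgs)))),
        class = "nrimpact_validation_error"
      )
    }
    warn(paste0(
      "dropping ", length(unique(diag$row)),
      " invalid observation row(s); see attr(x, 'diagnostics')"
    ))
    obs <- obs[-unique(diag$row), , drop = FALSE]
  }
  attr(obs, "diagnostics") <- diag
  attr(obs, "schema_version") <- schema_version
  obs
}

#' Validate observations against the schema invariants
#'
#' @param obs A tibble shaped like [read_observations()] output.
#' @return A tibble of diagnostics with columns `row`, `column`, `message`;
#'   zero rows when the table is fully valid.
#' @export
validate_observations <- function(obs) {
  problems <- list()
  note <- function(rows, column, message) {
    rows <- which(rows)
    if (length(rows) > 0) {
      problems[[length(problems) + 1]] <<- tibble(
        row = rows, column = column,
        message = paste0(column, " ", message)
      )
    }
  }
  isna <- function(x) is.na(x)
  note(isna(obs$study_id) | obs$study_id == "", "study_id", "is missing")
  note(isna(obs$crop), "crop", "is missing or not one of wheat/maize/rice")
  note(isna(obs$pathway), "pathway", "is missing or not one of NH3/N2O/NO3")
  note(isna(obs$n_source), "n_source", "is missing or not one of urea/OCF/IU/OA")
  note(isna(obs$placement), "placement", "is missing or not surface/subsurface")
  note(isna(obs$amendment), "amendment", "is missing or not none/mulch/biochar/inhibitor")
  note(isna(obs$n_rate) | obs$n_rate < 0, "n_rate", "must be >= 0")
  for (nm in c("loss_treat_mean", "loss_ctrl_mean")) {
    note(isna(obs[[nm]]) | obs[[nm]] < 0, nm, "must be a non-negative number")
  }
  for (nm in c("yield_treat_mean", "yield_ctrl_mean")) {
    note(isna(obs[[nm]]) | obs[[nm]] <= 0, nm, "must be a positive number")
  }
  for (nm in c("n_treat", "n_ctrl")) {
    note(isna(obs[[nm]]) | obs[[nm]] < 1, nm, "must be an integer >= 1")
  }
  for (arm in c("treat", "ctrl")) {
    kind <- obs[[paste0("disp_", arm, "_kind")]]
    val <- obs[[paste0("disp_", arm, "_value")]]
    lo <- obs[[paste0("disp_", arm, "_lower")]]
    up <- obs[[paste0("disp_", arm, "_upper")]]
    lev <- obs[[paste0("disp_", arm, "_level")]]
    note(isna(kind), paste0("disp_", arm, "_kind"), "is missing or not a known kind")
    sd_like <- !isna(kind) & kind %in% c("SD", "SE", "CV")
    note(sd_like & (isna(val) | val < 0), paste0("disp_", arm, "_value"),
      "must be >= 0 for SD/SE/CV")
    tv <- !isna(kind) & kind == "t_value"
    note(tv & isna(val), paste0("disp_", arm, "_value"), "must be given for t_value")
    pv <- !isna(kind) & kind == "p_value"
    note(pv & (isna(val) | val <= 0 | val > 1), paste0("disp_", arm, "_value"),
      "must lie in (0, 1] for p_value")
    ci <- !isna(kind) & kind == "CI"
    note(ci & (isna(lo) | isna(up) | up < lo), paste0("disp_", arm, "_upper"),
      "CI needs lower <= upper")
    note(ci & (isna(lev) | lev <= 0 | lev >= 1), paste0("disp_", arm, "_level"),
      "CI confidence level must lie in (0, 1)")
  }
  note(!is.na(obs$water_load) & obs$water_load < 0, "water_load", "must be >= 0")
  note(!is.na(obs$soil_ph) & (obs$soil_ph <= 0 | obs$soil_ph >= 14), "soil_ph",
    "must lie in (0, 14)")
  for (nm in c("som", "stn", "clay")) {
    note(!is.na(obs[[nm]]) & obs[[nm]] < 0, nm, "must be >= 0")
  }
  if (length(problems) == 0) {
    return(tibble(row = integer(), column = character(), message = character()))
  }
  dplyr::arrange(dplyr::bind_rows(problems), .data$row, .data$column)
}

#' Write an observation table
#'
#' Inverse of [read_observations()]: writes the documented CSV schema so a
#' read-write-read cycle is lossless.
#'
#' @param obs Observation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  readr::write_csv(obs, path, na = "", progress = FALSE)
  invisible(path)
}

#' Classify a nitrogen application rate
#'
#' Maps N rates (kg N ha^-1) into the three rate classes used throughout the
#' analysis: `R1` (reduced, below 150), `R2` (conventional, 150 up to 250)
#' and `R3` (excessive, 250 and above). Half-open intervals `[150, 250)` and
#' `[250, Inf)` make the partition total so records at round-number rates are
#' never dropped.
#'
#' @param n_rate Numeric vector of N rates, kg N ha^-1; all must be > 0
#'   (zero-N controls are not classified).
#' @return Factor with levels `R1`, `R2`, `R3`.
#' @examples
#' classify_rate(c(100, 150, 200, 250, 300))
#' @export
classify_rate <- function(n_rate) {
  if (!is.numeric(n_rate)) abort("n_rate must be numeric", class = "nrimpact_domain_error")
  if (any(is.na(n_rate)) || any(n_rate <= 0)) {
    abort("n_rate must be > 0 for every record (zero-N controls are not classified)",
      class = "nrimpact_domain_error"
    )
  }
  cut(n_rate,
    breaks = c(0, 150, 250, Inf), right = FALSE,
    labels = c("R1", "R2", "R3")
  )
}

#' Select the baseline practice subset
#'
#' The baseline against which mitigation strategies are judged: urea at the
#' conventional rate class (R2), surface-applied, with no amendments.
#'
#' @param obs Observation tibble.
#' @return The qualifying rows, with a `rate_class` column added.
#' @export
select_baseline <- function(obs) {
  out <- obs |>
    dplyr::mutate(rate_class = classify_rate(.data$n_rate)) |>
    dplyr::filter(
      .data$n_source == "urea",
      .data$rate_class == "R2",
      .data$placement == "surface",
      .data$amendment == "none"
    )
  if (nrow(out) == 0) {
    abort("no observations match the baseline (urea, R2, surface, no amendment)",
      class = "nrimpact_empty_group"
    )
  }
  out
}

#' Select the observation subset defining a mitigation strategy
#'
#' Each strategy varies exactly one management lever away from the baseline
#' (urea, R2, surface, none): `R1`/`R3` change the rate class; `OCF`, `IU`
#' and `OA` change the N source (at R2, surface, no amendment); `subsurface`
#' changes placement; `mulch`, `biochar` and `inhibitor` add the amendment.
#'
#' @param obs Observation tibble.
#' @param strategy One of `"R1"`, `"R3"`, `"OCF"`, `"IU"`, `"OA"`,
#'   `"subsurface"`, `"mulch"`, `"biochar"`, `"inhibitor"`.
#' @return The qualifying rows (possibly zero rows), with `rate_class` added.
#' @export
select_strategy <- function(obs, strategy) {
  strategy <- match.arg(strategy, strategy_levels())
  obs <- dplyr::mutate(obs, rate_class = classify_rate(.data$n_rate))
  base <- function(df) {
    dplyr::filter(df, .data$n_source == "urea", .data$rate_class == "R2",
      .data$placement == "surface", .data$amendment == "none")
  }
  switch(strategy,
    R1 = obs |> dplyr::filter(.data$n_source == "urea", .data$rate_class == "R1",
      .data$placement == "surface", .data$amendment == "none"),
    R3 = obs |> dplyr::filter(.data$n_source == "urea", .data$rate_class == "R3",
      .data$placement == "surface", .data$amendment == "none"),
    OCF = ,
    IU = ,
    OA = obs |> dplyr::filter(.data$n_source == strategy, .data$rate_class == "R2",
      .data$placement == "surface", .data$amendment == "none"),
    subsurface = obs |> dplyr::filter(.data$n_source == "urea",
      .data$rate_class == "R2", .data$placement == "subsurface",
      .data$amendment == "none"),
    mulch = ,
    biochar = ,
    inhibitor = obs |> dplyr::filter(.data$n_source == "urea",
      .data$rate_class == "R2", .data$placement == "surface",
      .data$amendment == strategy)
  )
}

#' Mitigation strategy labels
#'
#' @return Character vector of the nine strategy labels.
#' @export
strategy_levels <- function() {
  c("R1", "R3", "OCF", "IU", "OA", "subsurface", "mulch", "biochar", "inhibitor")
}
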