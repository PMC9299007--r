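# Classification of cropland cells into management-climate strata and
# aggregation of the areas eligible for each measure's intervention.

#' Classification thresholds for management strata
#'
#' Fertilization classes partition inorganic-N input: `[0, 40)` kg N
#' ha^-1 yr^-1 is unfertilized ("none"), `[40, 100]` medium, `(100, Inf)`
#' high. Manure input is split at 40 kg N ha^-1 yr^-1 into low and high.
#'
#' @param fert_none_max upper (exclusive) bound of the unfertilized class.
#' @param fert_medium_max upper (inclusive) bound of the medium class.
#' @param manure_high_min lower (inclusive) bound of the high-manure class.
#' @return Named list of thresholds.
#' @export
stratum_thresholds <- function(fert_none_max = 40, fert_medium_max = 100,
                               manure_high_min = 40) {
  check_number(fert_none_max, "fert_none_max", lower = 0)
  check_number(fert_medium_max, "fert_medium_max", lower = fert_none_max)
  check_number(manure_high_min, "manure_high_min", lower = 0)
  list(fert_none_max = fert_none_max, fert_medium_max = fert_medium_max,
       manure_high_min = manure_high_min)
}

validate_cells <- function(cells) {
  cells <- tibble::as_tibble(cells)
  required <- c("region_id", "climate", "area_ha", "n_fert_rate",
                "n_manure_rate", "tillage", "rotation", "residue_fate")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    stop_invalid("cell table lacks columns: %s",
                 paste(missing_cols, collapse = ", "))
  }
  check_enum(cells$climate, "climate", soc_climates)
  check_enum(cells$tillage, "tillage", soc_tillage_classes)
  check_enum(cells$rotation, "rotation", soc_rotation_classes)
  check_enum(cells$residue_fate, "residue_fate", soc_residue_classes)
  check_number(cells$area_ha, "area_ha", lower = 0)
  check_number(cells$n_fert_rate, "n_fert_rate", lower = 0)
  check_number(cells$n_manure_rate, "n_manure_rate", lower = 0)
  cells
}

#' Classify cropland cells into fertilization and manure classes
#'
#' @param cells cropland cell table with columns `region_id`, `climate`,
#'   `area_ha`, `n_fert_rate`, `n_manure_rate` (kg N ha^-1 yr^-1),
#'   `tillage` (`NT`/`IT`/`HT`), `rotation`, `residue_fate`.
#' @param thresholds see [stratum_thresholds()].
#' @return The cell table with `fert_class` and `manure_class` columns
#'   appended; every cell maps to exactly one class pair.
#' @export
classify_cells <- function(cells, thresholds = stratum_thresholds()) {
  cells <- validate_cells(cells)
  cells$fert_class <- ifelse(
    cells$n_fert_rate < thresholds$fert_none_max, "none",
    ifelse(cells$n_fert_rate <= thresholds$fert_medium_max, "medium", "high")
  )
  cells$manure_class <- ifelse(
    cells$n_manure_rate < thresholds$manure_high_min, "low", "high"
  )
  cells
}

#' Aggregate classified cells into management-climate strata
#'
#' @param cells output of [classify_cells()].
#' @return Tibble of strata (climate, fert_class, manure_class, tillage,
#'   rotation, residue_fate, region_id, area_ha); total area is conserved.
#' @export
aggregate_strata <- function(cells) {
  if (!all(c("fert_class", "manure_class") %in% names(cells))) {
    cells <- classify_cells(cells)
  }
  cells |>
    dplyr::group_by(.data$region_id, .data$climate, .data$fert_class,
                    .data$manure_class, .data$tillage, .data$rotation,
                    .data$residue_fate) |>
    dplyr::summarise(area_ha = sum(.data$area_ha), .groups = "drop")
}

#' Area eligible for a measure, per climate zone and intervention
#'
#' Maps current management to the intervention that would improve it:
#'
#' * `M1`: unfertilized strata can adopt inorganic fertilization (`IF-NF`);
#' * `M2`: unfertilized strata can adopt organic fertilization (`OF-NF`);
#'   fertilized strata with low manure input can substitute organic for
#'   inorganic fertilizer (`OF-IF`); high-manure strata are ineligible;
#' * `M3`: high-intensity tillage converts to no-till (`NT-HT`),
#'   intermediate tillage to no-till (`NT-IT`);
#' * `M4`: rotations without catch crops can add them (`CC`);
#' * `M5`: strata burning or removing residues can incorporate them
#'   (`CRES`).
#'
#' @param strata stratum table from [aggregate_strata()] (or classified
#'   cells; any table carrying the class columns and `area_ha`).
#' @param measure one of `soc_measures`.
#' @param by extra grouping columns kept in the output (e.g. `"region_id"`).
#' @return Tibble (`climate`, `intervention`, extra `by` columns,
#'   `area_ha`); the rows partition the measure-eligible subset.
#' @export
eligible_area <- function(strata, measure, by = character()) {
  measure <- match.arg(measure, soc_measures)
  strata <- tibble::as_tibble(strata)
  needed <- c("climate", "area_ha", "fert_class", "manure_class", "tillage",
              "rotation", "residue_fate")
  missing_cols <- setdiff(c(needed, by), names(strata))
  if (length(missing_cols) > 0) {
    stop_invalid("stratum table lacks columns: %s",
                 paste(missing_cols, collapse = ", "))
  }
  intervention <- switch(
    measure,
    M1 = ifelse(strata$fert_class == "none", "IF-NF", NA_character_),
    M2 = ifelse(strata$fert_class == "none", "OF-NF",
         ifelse(strata$manure_class == "low", "OF-IF", NA_character_)),
    M3 = ifelse(strata$tillage == "HT", "NT-HT",
         ifelse(strata$tillage == "IT", "NT-IT", NA_character_)),
    M4 = ifelse(strata$rotation == "without_catch_crops", "CC",
                NA_character_),
    M5 = ifelse(strata$residue_fate %in% c("burned", "removed"), "CRES",
                NA_character_)
  )
  strata$intervention <- intervention
  strata |>
    dplyr::filter(!is.na(.data$intervention)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("climate", "intervention", by)
    ))) |>
    dplyr::summarise(area_ha = sum(.data$area_ha), .groups = "drop")
}

#' Area-weighted composition of the stratified cropland
#'
#' @param strata stratum (or classified cell) table with `area_ha` and the
#'   management-class columns.
#' @return Tibble (`dimension`, `level`, `share`); within each dimension
#'   the shares sum to one.
#' @export
summarize_shares <- function(strata) {
  strata <- tibble::as_tibble(strata)
  total <- sum(strata$area_ha)
  if (!is.finite(total) || total <= 0) {
    stop_invalid("total area must be positive")
  }
  dims <- intersect(c("climate", "fert_class", "manure_class", "tillage",
                      "rotation", "residue_fate"), names(strata))
  out <- lapply(dims, function(dim) {
    strata |>
      dplyr::group_by(level = .data[[dim]]) |>
      dplyr::summarise(share = sum(.data$area_ha) / total,
                       .groups = "drop") |>
      dplyr::mutate(dimension = dim, .before = 1)
  })
  dplyr::bind_rows(out)
}
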