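# Regional budget of recyclable animal-manure carbon. Additional organic
# fertilization can only sequester carbon from manure that is not already
# applied somewhere: the supply is the nitrogen excreted minus the
# nitrogen already applied on cropland and grassland (incl. grazing),
# converted to stable carbon via a C:N ratio and a humification
# coefficient.

validate_manure_records <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("region_id", "n_excreted", "n_applied_cropland",
                "n_applied_grassland")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop_invalid("manure table lacks columns: %s",
                 paste(missing_cols, collapse = ", "))
  }
  for (col in required[-1]) check_number(records[[col]], col, lower = 0)
  records
}

#' Recyclable stable manure carbon per region
#'
#' The nitrogen surplus is the excreted N minus N already applied on
#' cropland and on grassland (including grazing deposition), clamped at
#' zero. Surplus N becomes organic carbon via the C:N ratio of the manure
#' organic fraction, of which the humification coefficient — the fraction
#' not decomposed within one year — is a stable input to soil carbon.
#'
#' @param records data frame with columns `region_id`, `n_excreted`,
#'   `n_applied_cropland`, `n_applied_grassland` (all kg N yr^-1).
#' @param cn_ratio carbon-to-nitrogen mass ratio of the manure organic
#'   fraction; default 10 (slurry is near 8, solid manure near 15).
#' @param hc humification coefficient in (0, 1]; default 0.5.
#' @return Tibble with `n_surplus` (kg N yr^-1), `c_surplus` (kg C yr^-1)
#'   and `stable_c_supply` (kg C yr^-1) per region.
#' @export
recyclable_manure_c <- function(records, cn_ratio = 10, hc = 0.5) {
  records <- validate_manure_records(records)
  check_number(cn_ratio, "cn_ratio", lower = 0, strict = TRUE)
  check_number(hc, "hc", lower = 0, strict = TRUE)
  if (hc > 1) stop_invalid("`hc` must be <= 1")
  n_surplus <- pmax(
    0,
    records$n_excreted - records$n_applied_cropland -
      records$n_applied_grassland
  )
  tibble::tibble(
    region_id = records$region_id,
    n_surplus = n_surplus,
    c_surplus = n_surplus * cn_ratio,
    stable_c_supply = n_surplus * cn_ratio * hc,
    cn_ratio = cn_ratio,
    humification_coefficient = hc
  )
}

#' Cap a raw organic-fertilization potential by the manure-carbon budget
#'
#' Applied per region before any zone aggregation: a region cannot
#' sequester more carbon through additional manure than its own
#' not-yet-recycled stable manure-carbon supply.
#'
#' @param raw_potential data frame with `region_id` and `potential_mton`
#'   (Mton C yr^-1).
#' @param budget output of [recyclable_manure_c()] (or any table with
#'   `region_id` and `stable_c_supply` in kg C yr^-1), aggregated to the
#'   same regions.
#' @return `raw_potential` with columns `budget_mton`, `capped_mton`
#'   (`min(raw, budget)`) and `cap_ratio` (`capped / raw`, 1 where raw is
#'   0) appended.
#' @export
cap_measure_potential <- function(raw_potential, budget) {
  raw_potential <- tibble::as_tibble(raw_potential)
  budget <- tibble::as_tibble(budget)
  if (!all(c("region_id", "potential_mton") %in% names(raw_potential))) {
    stop_invalid("`raw_potential` needs columns region_id, potential_mton")
  }
  if (!all(c("region_id", "stable_c_supply") %in% names(budget))) {
    stop_invalid("`budget` needs columns region_id, stable_c_supply")
  }
  budget <- budget |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(stable_c_supply = sum(.data$stable_c_supply),
                     .groups = "drop")
  missing_regions <- setdiff(raw_potential$region_id, budget$region_id)
  if (length(missing_regions) > 0) {
    stop_invalid("no manure budget for region(s): %s",
                 paste(missing_regions, collapse = ", "))
  }
  out <- dplyr::left_join(raw_potential, budget, by = "region_id")
  out$budget_mton <- kg_to_mton(out$stable_c_supply)
  out$capped_mton <- pmin(out$potential_mton, out$budget_mton)
  out$cap_ratio <- ifelse(out$potential_mton > 0,
                          out$capped_mton / out$potential_mton, 1)
  out$stable_c_supply <- NULL
  out
}
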