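# Packaged reference tables: the pooled annual SOC stock changes per
# intervention and climate zone, and the published per-measure
# sequestration potentials with their Monte-Carlo bounds. Both ship as
# plain CSV under inst/extdata and carry the printed (rounded) values.

#' Packaged pooled SOC effect table
#'
#' Weighted mean annual SOC stock changes (t C ha^-1 yr^-1) with standard
#' errors per management intervention and climate zone, for the top
#' 20-30 cm over a 20-yr horizon, as pooled from 14 meta-studies. The
#' `"other"` climate holds the all-zone pooled value used as fallback for
#' zones without their own estimate.
#'
#' @return Tibble with `measure`, `intervention`, `climate`, `mean`, `se`.
#' @export
soc_effect_table <- function() {
  path <- system.file("extdata", "table2_effects.csv",
                      package = "socpotential", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  tibble::tibble(
    measure = tab$measure,
    intervention = tab$intervention,
    climate = tab$climate,
    mean = tab$mean_tC_ha_yr,
    se = tab$se_tC_ha_yr
  )
}

#' Packaged per-measure sequestration potential table
#'
#' Potential C sequestration (Mton C yr^-1) per measure and climate zone
#' with 0.01/0.99 Monte-Carlo bounds, including the manure-capped organic
#' fertilization measure `M2cor` and the `"all"` row per measure.
#'
#' @return Tibble with `measure`, `climate`, `potential_mton`, `q01`,
#'   `q99`.
#' @export
soc_potential_table <- function() {
  path <- system.file("extdata", "table3_potentials.csv",
                      package = "socpotential", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  tibble::tibble(
    measure = tab$measure,
    climate = tab$climate,
    potential_mton = tab$mean_mton,
    q01 = tab$q01_mton,
    q99 = tab$q99_mton
  )
}

#' Global per-measure potentials for scenario combination
#'
#' Extracts the `"all"` rows of [soc_potential_table()] for the five
#' measures, with organic fertilization represented by its manure-capped
#' version (`M2cor`, relabelled `M2`).
#'
#' @param use_m2cor cap organic fertilization by the manure budget
#'   (default `TRUE`); `FALSE` selects the uncapped `M2` row.
#' @return Tibble with one row per measure (`measure`, `potential_mton`,
#'   `q01`, `q99`), ready for [combine_max_complementarity()] /
#'   [combine_rank_weighted()].
#' @export
soc_global_potentials <- function(use_m2cor = TRUE) {
  tab <- soc_potential_table()
  keep <- c("M1", if (use_m2cor) "M2cor" else "M2", "M3", "M4", "M5")
  out <- tab[tab$climate == "all" & tab$measure %in% keep, ]
  out$measure[out$measure == "M2cor"] <- "M2"
  out[order(out$measure), c("measure", "potential_mton", "q01", "q99")]
}
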