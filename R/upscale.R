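# Upscaling: eligible areas x pooled annual SOC stock changes give
# per-zone sequestration potentials (Mton C yr^-1); uncertainty is
# propagated by Monte-Carlo sampling of the effect cells, and measures are
# combined under complementarity rules.

# join areas with effects, falling back to the all-zone ("other") cell
# where a zone-specific effect is missing
join_effects <- function(area_table, effects, fallback_other = TRUE) {
  area_table <- tibble::as_tibble(area_table)
  effects <- tibble::as_tibble(effects)
  if (!all(c("climate", "intervention", "area_ha") %in% names(area_table))) {
    stop_invalid("`area_table` needs columns climate, intervention, area_ha")
  }
  if (!all(c("intervention", "climate", "mean", "se") %in% names(effects))) {
    stop_invalid("`effects` needs columns intervention, climate, mean, se")
  }
  eff <- effects[, c("intervention", "climate", "mean", "se")]
  joined <- dplyr::left_join(area_table, eff,
                             by = c("intervention", "climate"))
  miss <- is.na(joined$mean)
  if (any(miss) && fallback_other) {
    other <- eff[eff$climate == "other", c("intervention", "mean", "se")]
    names(other) <- c("intervention", "mean_other", "se_other")
    joined <- dplyr::left_join(joined, other, by = "intervention")
    joined$mean[miss] <- joined$mean_other[miss]
    joined$se[miss] <- joined$se_other[miss]
    joined$mean_other <- joined$se_other <- NULL
    miss <- is.na(joined$mean)
  }
  if (any(miss)) {
    bad <- unique(paste0(joined$intervention[miss], "/", joined$climate[miss]))
    stop_invalid("no effect size for cell(s): %s (and no all-zone fallback)",
                 paste(bad, collapse = ", "))
  }
  joined
}

#' Deterministic sequestration potential of a measure per climate zone
#'
#' Multiplies each eligible area by the pooled annual SOC stock change of
#' its assigned intervention and sums within climate zones:
#' potential (Mton C yr^-1) = sum over strata of
#' area (ha) x effect (t C ha^-1 yr^-1) x 1e-6.
#' Zones lacking a zone-specific effect use the all-zone (`"other"`)
#' pooled effect.
#'
#' @param area_table tibble with `climate`, `intervention`, `area_ha` (and
#'   optionally extra keys such as `region_id`, preserved in `by`).
#' @param effects pooled effect table with `intervention`, `climate`,
#'   `mean`, `se` (t C ha^-1 yr^-1).
#' @param by extra grouping columns to keep (e.g. `"region_id"`).
#' @param fallback_other use the `"other"` cell for missing zones
#'   (default `TRUE`).
#' @return Tibble (`climate`, `by` columns, `potential_mton`).
#' @export
measure_potential <- function(area_table, effects, by = character(),
                              fallback_other = TRUE) {
  joined <- join_effects(area_table, effects, fallback_other)
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("climate", by)))) |>
    dplyr::summarise(
      potential_mton = sum(.data$area_ha * .data$mean) * 1e-6,
      .groups = "drop"
    )
}

#' Monte-Carlo uncertainty of a measure's sequestration potential
#'
#' Every draw samples each effect cell independently from
#' `Normal(mean, se)`, recomputes the per-zone potential, and the 0.01 /
#' 0.99 quantiles of the draws give the uncertainty bounds. The reported
#' central value is the deterministic [measure_potential()]. The `"all"`
#' row sums the zone potentials within each draw, so its bounds are
#' quantiles of the summed draws.
#'
#' @inheritParams measure_potential
#' @param n_mc number of Monte-Carlo draws (>= 2); default 1000.
#' @param seed integer seed for reproducibility (optional but
#'   recommended).
#' @param probs two quantile probabilities; default `c(0.01, 0.99)`.
#' @param retain_draws keep the draw matrix as an attribute `"draws"`
#'   (zones in columns, draws in rows).
#' @return Tibble (`climate` incl. `"all"`, `potential_mton`, `q01`,
#'   `q99`).
#' @export
monte_carlo_potential <- function(area_table, effects, n_mc = 1000,
                                  seed = NULL, probs = c(0.01, 0.99),
                                  fallback_other = TRUE,
                                  retain_draws = FALSE) {
  if (!is.numeric(n_mc) || n_mc < 2) stop_invalid("`n_mc` must be >= 2")
  joined <- join_effects(area_table, effects, fallback_other)
  check_number(joined$se, "se", lower = 0)
  if (!is.null(seed)) set.seed(seed)

  # one sampled effect per joined row and draw; rows sharing an effect
  # cell must move together, so sample per unique (intervention, climate)
  cell_key <- paste(joined$intervention, joined$climate, sep = "|")
  cells <- !duplicated(cell_key)
  cell_mean <- joined$mean[cells]
  cell_se <- joined$se[cells]
  idx <- match(cell_key, cell_key[cells])

  zones <- sort(unique(joined$climate))
  zone_idx <- match(joined$climate, zones)
  area <- joined$area_ha

  draws <- matrix(0, nrow = n_mc, ncol = length(zones),
                  dimnames = list(NULL, zones))
  eff_draw <- matrix(
    rnorm(n_mc * length(cell_mean), mean = cell_mean, sd = cell_se),
    nrow = length(cell_mean), ncol = n_mc
  )
  # potential per draw: area-weighted sum of sampled effects within zone
  for (z in seq_along(zones)) {
    rows <- which(zone_idx == z)
    draws[, z] <- as.numeric(area[rows] %*%
                               eff_draw[idx[rows], , drop = FALSE]) * 1e-6
  }

  det <- measure_potential(area_table, effects, fallback_other = fallback_other)
  qs <- apply(draws, 2, quantile, probs = probs, names = FALSE, type = 7)
  out <- tibble::tibble(
    climate = zones,
    potential_mton = det$potential_mton[match(zones, det$climate)],
    q01 = unname(qs[1, ]),
    q99 = unname(qs[2, ])
  )
  all_draws <- rowSums(draws)
  all_q <- quantile(all_draws, probs = probs, names = FALSE, type = 7)
  out <- dplyr::bind_rows(out, tibble::tibble(
    climate = "all",
    potential_mton = sum(det$potential_mton),
    q01 = all_q[1],
    q99 = all_q[2]
  ))
  if (retain_draws) {
    attr(out, "draws") <- cbind(draws, all = all_draws)
  }
  out
}

check_scenario_input <- function(potentials) {
  potentials <- tibble::as_tibble(potentials)
  needed <- c("measure", "potential_mton", "q01", "q99")
  if (!all(needed %in% names(potentials))) {
    stop_invalid("scenario input needs columns %s",
                 paste(needed, collapse = ", "))
  }
  if (nrow(potentials) != 5 ||
      length(unique(potentials$measure)) != 5) {
    stop_invalid(
      "scenario combination needs exactly the five measures, got: %s",
      paste(potentials$measure, collapse = ", ")
    )
  }
  potentials
}

#' Combine measures assuming maximum complementarity
#'
#' Treats the five per-measure global potentials (the organic-fertilizer
#' measure entering as its manure-capped version) as fully additive: the
#' total is the plain sum of means and the bounds are the sums of the
#' per-measure 0.01 / 0.99 quantiles.
#'
#' @param potentials tibble with one row per measure: `measure`,
#'   `potential_mton`, `q01`, `q99`.
#' @return A `scenario_result` list: `rule`, `total`, `low`, `high`,
#'   `ranks`, `weights`.
#' @export
combine_max_complementarity <- function(potentials) {
  potentials <- check_scenario_input(potentials)
  structure(list(
    rule = "max_complementarity",
    total = sum(potentials$potential_mton),
    low = sum(potentials$q01),
    high = sum(potentials$q99),
    ranks = potentials$measure[order(-potentials$potential_mton,
                                     potentials$measure)],
    weights = setNames(rep(1, 5), potentials$measure)
  ), class = "scenario_result")
}

#' Combine measures with rank-declining weights
#'
#' A conservative alternative to full additivity: measures are sorted from
#' highest to lowest mean potential and the k-th ranked measure
#' contributes `1/k` of its value. Bounds apply the same mean-derived
#' ranks and weights to the per-measure 0.01 / 0.99 quantiles. Ties are
#' broken by measure label order.
#'
#' @inheritParams combine_max_complementarity
#' @return A `scenario_result` list.
#' @export
combine_rank_weighted <- function(potentials) {
  potentials <- check_scenario_input(potentials)
  ord <- order(-potentials$potential_mton, potentials$measure)
  ranked <- potentials[ord, ]
  w <- 1 / seq_len(nrow(ranked))
  structure(list(
    rule = "rank_weighted",
    total = sum(ranked$potential_mton * w),
    low = sum(ranked$q01 * w),
    high = sum(ranked$q99 * w),
    ranks = ranked$measure,
    weights = setNames(w, ranked$measure)
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario (%s): %.0f Mton C yr^-1 [%.0f, %.0f]\n",
              x$rule, x$total, x$low, x$high))
  cat("  ranks:", paste(x$ranks, collapse = " > "), "\n")
  cat("  weights:", paste(sprintf("%s=%.2f", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  invisible(x)
}
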