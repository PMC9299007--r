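# End-to-end pipeline: harmonize -> stratify -> budget -> upscale, with
# CSV interchange, collected schema validation and a run manifest so a
# rerun with identical inputs and seed reproduces identical outputs.

#' Read raw effect-size records from CSV
#'
#' Expected columns: `source_id`, `measure`, `intervention`, `climate`,
#' `metric`, `value`, `variation_kind`, `variation_value`,
#' `variation_value2`, `n_pairs`, `depth_m`, `duration_yr`.
#'
#' @param path CSV file path (UTF-8, header required).
#' @return Validated tibble of effect-size records.
#' @export
read_effect_records <- function(path) {
  validate_effect_records(readr::read_csv(path, show_col_types = FALSE))
}

#' Read a cropland cell table from CSV
#'
#' Expected columns: `region_id`, `climate`, `area_ha`, `n_fert_rate`,
#' `n_manure_rate`, `tillage`, `rotation`, `residue_fate`.
#'
#' @inheritParams read_effect_records
#' @return Validated tibble of cropland cells.
#' @export
read_cropland_cells <- function(path) {
  validate_cells(readr::read_csv(path, show_col_types = FALSE))
}

#' Read regional manure nitrogen records from CSV
#'
#' Expected columns: `region_id`, `n_excreted`, `n_applied_cropland`,
#' `n_applied_grassland` (kg N yr^-1).
#'
#' @inheritParams read_effect_records
#' @return Validated tibble of manure region records.
#' @export
read_manure_records <- function(path) {
  validate_manure_records(readr::read_csv(path, show_col_types = FALSE))
}

check_table <- function(tab, file, numeric_min, enums, required) {
  violations <- list()
  add <- function(row, column, message) {
    violations[[length(violations) + 1]] <<- tibble::tibble(
      file = file, row = row, column = column, message = message
    )
  }
  for (col in setdiff(required, names(tab))) {
    add(NA_integer_, col, "missing required column")
  }
  for (col in intersect(names(numeric_min), names(tab))) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(x) | x < numeric_min[[col]])
    for (r in bad) {
      add(r, col, sprintf("must be a number >= %s", numeric_min[[col]]))
    }
  }
  for (col in intersect(names(enums), names(tab))) {
    vals <- as.character(tab[[col]])
    bad <- which(!is.na(vals) & !vals %in% enums[[col]])
    for (r in bad) {
      add(r, col, sprintf("invalid label '%s'; allowed: %s", vals[r],
                          paste(enums[[col]], collapse = ", ")))
    }
  }
  violations
}

#' Validate pipeline input files without failing fast
#'
#' Runs column-level type, range and enum-label checks on the CSV inputs
#' and collects every violation instead of stopping at the first.
#'
#' @param paths named character vector or list; recognised names are
#'   `cells`, `effects`, `manure`.
#' @return Tibble of violations (`file`, `row`, `column`, `message`);
#'   zero rows when everything is valid.
#' @export
validate_inputs <- function(paths) {
  out <- list()
  if (!is.null(paths$effects)) {
    tab <- readr::read_csv(paths$effects, show_col_types = FALSE)
    out <- c(out, check_table(
      tab, paths$effects,
      numeric_min = list(value = -Inf, depth_m = 1e-12, n_pairs = 1),
      enums = list(measure = soc_measures,
                   intervention = soc_interventions,
                   climate = soc_climates, metric = soc_metrics,
                   variation_kind = c("SD", "SE", "CI95")),
      required = c("source_id", "measure", "intervention", "climate",
                   "metric", "value", "depth_m", "duration_yr")
    ))
  }
  if (!is.null(paths$cells)) {
    tab <- readr::read_csv(paths$cells, show_col_types = FALSE)
    out <- c(out, check_table(
      tab, paths$cells,
      numeric_min = list(area_ha = 0, n_fert_rate = 0, n_manure_rate = 0),
      enums = list(climate = soc_climates, tillage = soc_tillage_classes,
                   rotation = soc_rotation_classes,
                   residue_fate = soc_residue_classes),
      required = c("region_id", "climate", "area_ha", "n_fert_rate",
                   "n_manure_rate", "tillage", "rotation", "residue_fate")
    ))
  }
  if (!is.null(paths$manure)) {
    tab <- readr::read_csv(paths$manure, show_col_types = FALSE)
    out <- c(out, check_table(
      tab, paths$manure,
      numeric_min = list(n_excreted = 0, n_applied_cropland = 0,
                         n_applied_grassland = 0),
      enums = list(),
      required = c("region_id", "n_excreted", "n_applied_cropland",
                   "n_applied_grassland")
    ))
  }
  if (length(out) == 0) {
    return(tibble::tibble(file = character(), row = integer(),
                          column = character(), message = character()))
  }
  dplyr::bind_rows(out)
}

# organic-fertilization potential capped per region by the manure-carbon
# budget, deterministically and per Monte-Carlo draw
m2cor_potential <- function(area_table, effects, budget, n_mc = 1000,
                            probs = c(0.01, 0.99)) {
  joined <- join_effects(area_table, effects)
  budget <- budget |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(budget_mton = kg_to_mton(sum(.data$stable_c_supply)),
                     .groups = "drop")
  missing_regions <- setdiff(joined$region_id, budget$region_id)
  if (length(missing_regions) > 0) {
    stop_invalid("no manure budget for region(s): %s",
                 paste(missing_regions, collapse = ", "))
  }
  b <- budget$budget_mton[match(unique(joined$region_id),
                                budget$region_id)]
  regions <- unique(joined$region_id)
  reg_idx <- match(joined$region_id, regions)
  zones <- sort(unique(joined$climate))
  zone_idx <- match(joined$climate, zones)

  cap_zone_sums <- function(contrib) {
    raw <- as.numeric(tapply(contrib, reg_idx, sum))
    ratio <- ifelse(raw > 0, pmin(1, b / raw), 1)
    scaled <- contrib * ratio[reg_idx]
    as.numeric(tapply(scaled, zone_idx, sum))
  }

  det <- cap_zone_sums(joined$area_ha * joined$mean * 1e-6)

  cell_key <- paste(joined$intervention, joined$climate, sep = "|")
  cells <- !duplicated(cell_key)
  idx <- match(cell_key, cell_key[cells])
  draws <- matrix(0, n_mc, length(zones), dimnames = list(NULL, zones))
  eff_draw <- matrix(
    rnorm(n_mc * sum(cells), joined$mean[cells], joined$se[cells]),
    nrow = sum(cells)
  )
  for (d in seq_len(n_mc)) {
    draws[d, ] <- cap_zone_sums(joined$area_ha * eff_draw[idx, d] * 1e-6)
  }
  qs <- apply(draws, 2, quantile, probs = probs, names = FALSE, type = 7)
  out <- tibble::tibble(climate = zones, potential_mton = det,
                        q01 = unname(qs[1, ]), q99 = unname(qs[2, ]))
  all_draws <- rowSums(draws)
  dplyr::bind_rows(out, tibble::tibble(
    climate = "all",
    potential_mton = sum(det),
    q01 = quantile(all_draws, probs[1], names = FALSE, type = 7),
    q99 = quantile(all_draws, probs[2], names = FALSE, type = 7)
  ))
}

#' Pipeline configuration
#'
#' @param synthetic generate inputs with the packaged generators
#'   (default); otherwise `inputs` must name the three CSVs.
#' @param generator a [generator_config()] used when `synthetic = TRUE`.
#' @param inputs named list of CSV paths (`cells`, `effects`, `manure`)
#'   for non-synthetic runs.
#' @param n_mc Monte-Carlo draws per measure; default 1000.
#' @param cn_ratio,hc manure carbon budget parameters, see
#'   [recyclable_manure_c()].
#' @param seed master seed; overrides `generator$seed` and seeds the
#'   Monte-Carlo streams.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = TRUE,
                            generator = generator_config(),
                            inputs = list(),
                            n_mc = 1000,
                            cn_ratio = 10,
                            hc = 0.5,
                            seed = 42) {
  if (!synthetic) {
    need <- setdiff(c("cells", "effects", "manure"), names(inputs))
    if (length(need) > 0) {
      stop_invalid("non-synthetic run needs input paths: %s",
                   paste(need, collapse = ", "))
    }
  }
  structure(list(synthetic = synthetic, generator = generator,
                 inputs = inputs, n_mc = n_mc, cn_ratio = cn_ratio,
                 hc = hc, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full upscaling pipeline
#'
#' Executes harmonization, stratification, the manure budget and the
#' Monte-Carlo upscaling in order and (optionally) writes the outputs —
#' effect table, stratum table, shares report, budget table, potential
#' table, scenario report and run manifest — to a directory. All tables
#' are computed before anything is written, so a failing stage leaves no
#' partial output tree.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created); `NULL` skips writing.
#' @return Invisibly, a list with elements `effects`, `strata`, `shares`,
#'   `budgets`, `potentials`, `scenarios` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  gen <- config$generator
  gen$seed <- config$seed

  if (config$synthetic) {
    cells <- generate_cells(gen)
    eff <- generate_effect_records(gen)
    records <- eff$records
    manure <- generate_manure_records(gen)
    digests <- list()
  } else {
    cells <- read_cropland_cells(config$inputs$cells)
    records <- read_effect_records(config$inputs$effects)
    manure <- read_manure_records(config$inputs$manure)
    digests <- lapply(config$inputs, function(p)
      unname(tools::md5sum(p)))
  }

  effects <- build_effect_table(records)
  strata <- aggregate_strata(classify_cells(cells))
  shares <- summarize_shares(strata)
  budgets <- recyclable_manure_c(manure, cn_ratio = config$cn_ratio,
                                 hc = config$hc)

  potentials <- list()
  for (m in soc_measures) {
    if (m == "M2") {
      area <- eligible_area(strata, "M2", by = "region_id")
      raw <- monte_carlo_potential(
        area[, c("climate", "intervention", "area_ha")], effects,
        n_mc = config$n_mc, seed = sub_seed(config$seed, 10)
      )
      set.seed(sub_seed(config$seed, 11))
      capped <- m2cor_potential(area, effects, budgets,
                                n_mc = config$n_mc)
      potentials$M2 <- dplyr::mutate(raw, measure = "M2", .before = 1)
      potentials$M2cor <- dplyr::mutate(capped, measure = "M2cor",
                                        .before = 1)
    } else {
      area <- eligible_area(strata, m)
      pot <- monte_carlo_potential(
        area, effects, n_mc = config$n_mc,
        seed = sub_seed(config$seed, 10 + match(m, soc_measures))
      )
      potentials[[m]] <- dplyr::mutate(pot, measure = m, .before = 1)
    }
  }
  potentials <- dplyr::bind_rows(potentials)

  globals <- potentials |>
    dplyr::filter(.data$climate == "all",
                  .data$measure %in% c("M1", "M2cor", "M3", "M4", "M5")) |>
    dplyr::mutate(measure = ifelse(.data$measure == "M2cor", "M2",
                                   .data$measure)) |>
    dplyr::select("measure", "potential_mton", "q01", "q99")
  scenarios <- list(
    max_complementarity = combine_max_complementarity(globals),
    rank_weighted = combine_rank_weighted(globals)
  )

  manifest <- list(
    package = "socpotential",
    version = as.character(utils::packageVersion("socpotential")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    synthetic = config$synthetic,
    n_mc = config$n_mc,
    cn_ratio = config$cn_ratio,
    hc = config$hc,
    generator = if (config$synthetic) {
      unclass(gen)[!vapply(gen, is.function, logical(1))]
    },
    input_digests = digests,
    row_counts = list(
      cells = nrow(cells), effect_records = nrow(records),
      manure_regions = nrow(manure), effect_cells = nrow(effects),
      strata = nrow(strata), potentials = nrow(potentials)
    )
  )

  result <- list(effects = effects, strata = strata, shares = shares,
                 budgets = budgets, potentials = potentials,
                 scenarios = scenarios, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    eff_out <- effects
    names(eff_out)[names(eff_out) == "mean"] <- "mean_tC_ha_yr"
    names(eff_out)[names(eff_out) == "se"] <- "se_tC_ha_yr"
    readr::write_csv(eff_out, file.path(out_dir, "effects.csv"))
    readr::write_csv(strata, file.path(out_dir, "strata.csv"))
    readr::write_csv(budgets, file.path(out_dir, "budgets.csv"))
    readr::write_csv(potentials, file.path(out_dir, "potentials.csv"))
    jsonlite::write_json(
      split(shares[, c("level", "share")], shares$dimension),
      file.path(out_dir, "shares.json"), dataframe = "rows", digits = NA
    )
    jsonlite::write_json(
      lapply(scenarios, unclass),
      file.path(out_dir, "scenarios.json"), auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(result)
}
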