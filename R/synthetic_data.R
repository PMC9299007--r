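# Seeded generators for synthetic cropland cells, effect-size records and
# manure regions. The defaults emulate the marginal composition of the
# global cropland layers the upscaling rests on (climate 30/19/30/21%,
# 45% high-intensity tillage, 8% no-till, 25% residue burning, 72%
# rotations without catch crops, 13% of area highly fertilized with both
# inorganic and organic inputs, total area 1,416,912 kha, manure excretion
# 129 Tg N yr^-1 with >= 90% already recycled), so the full pipeline can
# run and be tested without any spatial downloads.

# independent sub-streams per generated table, all derived from one seed
sub_seed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483646L + 1L
}

#' Configuration of the synthetic-data generators
#'
#' @param n_cells number of cropland cells to generate.
#' @param total_area_kha total cropland area in thousand hectares;
#'   default 1,416,912 kha (the global cropland area the pipeline
#'   upscales over).
#' @param climate_shares named area shares per climate zone; must sum
#'   to 1.
#' @param tillage_shares named area shares for `HT`/`NT`/`IT`.
#' @param residue_shares named area shares for
#'   `burned`/`incorporated`/`removed`.
#' @param no_catch_crop_share share of area in rotations without catch
#'   crops.
#' @param fert_class_shares named shares of the `none`/`medium`/`high`
#'   inorganic-fertilization classes.
#' @param high_high_fert_share joint share of area that is highly
#'   fertilized both inorganically and with manure; must not exceed the
#'   `high` fertilization share.
#' @param manure_high_share_other probability of high manure input in the
#'   non-high fertilization classes.
#' @param n_regions number of regions (countries) cells and manure
#'   records are assigned to.
#' @param effect_truth truth table for effect-record generation
#'   (`intervention`, `climate`, `mean` in t C ha^-1 yr^-1); default is
#'   the packaged pooled-effect table's zone cells.
#' @param effect_k records generated per truth cell.
#' @param effect_cv within-cell coefficient of variation of the generated
#'   study SDs.
#' @param effect_n_pairs paired comparisons per generated record.
#' @param total_excretion_kg total manure N excretion, kg N yr^-1;
#'   default 1.29e11 (129 Tg).
#' @param recycling_fraction fraction of excreted N already applied on
#'   cropland or grassland, in `[0, 1]`; default 0.9.
#' @param cropland_application_share share of the applied N that goes to
#'   cropland (the rest to grassland incl. grazing).
#' @param seed master seed; each generated table uses its own sub-stream.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_cells = 5000,
                             total_area_kha = 1416912,
                             climate_shares = c(tropical = 0.30,
                                                temperate = 0.19,
                                                subtropical = 0.30,
                                                other = 0.21),
                             tillage_shares = c(HT = 0.45, NT = 0.08,
                                                IT = 0.47),
                             residue_shares = c(burned = 0.25,
                                                incorporated = 0.60,
                                                removed = 0.15),
                             no_catch_crop_share = 0.72,
                             fert_class_shares = c(none = 0.25,
                                                   medium = 0.50,
                                                   high = 0.25),
                             high_high_fert_share = 0.13,
                             manure_high_share_other = 0.10,
                             n_regions = 20,
                             effect_truth = NULL,
                             effect_k = 4,
                             effect_cv = 0.3,
                             effect_n_pairs = 12,
                             total_excretion_kg = 1.29e11,
                             recycling_fraction = 0.9,
                             cropland_application_share = 0.55,
                             seed = 42) {
  check_number(n_cells, "n_cells", lower = 1)
  check_number(total_area_kha, "total_area_kha", lower = 0, strict = TRUE)
  for (nm in c("climate_shares", "tillage_shares", "residue_shares",
               "fert_class_shares")) {
    shares <- get(nm)
    check_number(shares, nm, lower = 0)
    if (abs(sum(shares) - 1) > 1e-9) {
      stop_invalid("`%s` must sum to 1", nm)
    }
  }
  check_enum(names(climate_shares), "climate_shares", soc_climates)
  check_enum(names(tillage_shares), "tillage_shares", soc_tillage_classes)
  check_enum(names(residue_shares), "residue_shares", soc_residue_classes)
  check_enum(names(fert_class_shares), "fert_class_shares", soc_fert_classes)
  check_number(no_catch_crop_share, "no_catch_crop_share", lower = 0)
  if (no_catch_crop_share > 1) stop_invalid("`no_catch_crop_share` > 1")
  if (high_high_fert_share > fert_class_shares[["high"]]) {
    stop_invalid(paste0("`high_high_fert_share` cannot exceed the high",
                        " fertilization share"))
  }
  if (recycling_fraction < 0 || recycling_fraction > 1) {
    stop_invalid("`recycling_fraction` must be in [0, 1]")
  }
  if (cropland_application_share < 0 || cropland_application_share > 1) {
    stop_invalid("`cropland_application_share` must be in [0, 1]")
  }
  check_number(n_regions, "n_regions", lower = 1)
  check_number(effect_k, "effect_k", lower = 1)
  check_number(effect_cv, "effect_cv", lower = 0, strict = TRUE)
  check_number(effect_n_pairs, "effect_n_pairs", lower = 1)
  check_number(total_excretion_kg, "total_excretion_kg", lower = 0)
  structure(list(
    n_cells = as.integer(n_cells),
    total_area_kha = total_area_kha,
    climate_shares = climate_shares,
    tillage_shares = tillage_shares,
    residue_shares = residue_shares,
    no_catch_crop_share = no_catch_crop_share,
    fert_class_shares = fert_class_shares,
    high_high_fert_share = high_high_fert_share,
    manure_high_share_other = manure_high_share_other,
    n_regions = as.integer(n_regions),
    effect_truth = effect_truth,
    effect_k = as.integer(effect_k),
    effect_cv = effect_cv,
    effect_n_pairs = as.integer(effect_n_pairs),
    total_excretion_kg = total_excretion_kg,
    recycling_fraction = recycling_fraction,
    cropland_application_share = cropland_application_share,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# rate draw from a lognormal restricted to a class interval [lo, hi)
rate_in_class <- function(n, lo, hi, meanlog, sdlog) {
  p_lo <- plnorm(lo, meanlog, sdlog)
  p_hi <- plnorm(hi, meanlog, sdlog)
  qlnorm(runif(n, p_lo, p_hi), meanlog, sdlog)
}

#' Generate a synthetic cropland cell table
#'
#' Categorical attributes are drawn independently per configured share
#' (except fertilizer and manure classes, drawn jointly to hit the
#' high-high target), cell areas follow a symmetric Dirichlet rescaled so
#' their sum equals the configured total exactly, and N rates are drawn
#' from class-truncated lognormals so the induced fertilization classes
#' match the configured marginals.
#'
#' @param config a [generator_config()].
#' @return Tibble of cropland cells (see [classify_cells()] for columns).
#' @export
generate_cells <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(sub_seed(config$seed, 1))
  n <- config$n_cells

  climate <- sample(names(config$climate_shares), n, replace = TRUE,
                    prob = config$climate_shares)
  tillage <- sample(names(config$tillage_shares), n, replace = TRUE,
                    prob = config$tillage_shares)
  residue <- sample(names(config$residue_shares), n, replace = TRUE,
                    prob = config$residue_shares)
  rotation <- sample(soc_rotation_classes, n, replace = TRUE,
                     prob = c(1 - config$no_catch_crop_share,
                              config$no_catch_crop_share))

  fert_class <- sample(names(config$fert_class_shares), n, replace = TRUE,
                       prob = config$fert_class_shares)
  p_high_given_high <- config$high_high_fert_share /
    config$fert_class_shares[["high"]]
  p_high_manure <- ifelse(fert_class == "high", p_high_given_high,
                          config$manure_high_share_other)
  manure_class <- ifelse(runif(n) < p_high_manure, "high", "low")

  n_fert <- numeric(n)
  n_fert[fert_class == "none"] <-
    rate_in_class(sum(fert_class == "none"), 0, 40, log(60), 0.7)
  n_fert[fert_class == "medium"] <-
    rate_in_class(sum(fert_class == "medium"), 40, 100, log(60), 0.7)
  n_fert[fert_class == "high"] <-
    rate_in_class(sum(fert_class == "high"), 100, 400, log(60), 0.7)
  n_manure <- numeric(n)
  n_manure[manure_class == "low"] <-
    rate_in_class(sum(manure_class == "low"), 0, 40, log(15), 1.0)
  n_manure[manure_class == "high"] <-
    rate_in_class(sum(manure_class == "high"), 40, 300, log(15), 1.0)

  area <- rgamma(n, shape = 1, rate = 1)
  area <- area / sum(area) * config$total_area_kha * 1000

  tibble::tibble(
    region_id = sprintf("R%02d", sample.int(config$n_regions, n,
                                            replace = TRUE)),
    climate = climate,
    area_ha = area,
    n_fert_rate = n_fert,
    n_manure_rate = n_manure,
    tillage = tillage,
    rotation = rotation,
    residue_fate = residue
  )
}

default_effect_truth <- function() {
  tab <- soc_effect_table()
  tab <- tab[tab$climate != "other", c("intervention", "climate", "mean")]
  tab
}

#' Generate synthetic effect-size records with known pooled truth
#'
#' For each truth cell (intervention x climate x true mean), `effect_k`
#' study records are drawn with observed means `Normal(truth, sd/sqrt(n))`
#' where `sd = effect_cv * |truth|`. Records cycle through the reporting
#' metrics (annual stock with SE, cumulative stock with SD and n over 20
#' yr, cumulative concentration with a 95% CI at 1400 kg m^-3 bulk
#' density and 0.3 m depth), constructed to harmonize back to the same
#' annual truth, so the full conversion chain is exercised.
#'
#' @param config a [generator_config()]; `config$effect_truth` may supply
#'   a custom truth table (`intervention`, `climate`, `mean`).
#' @return List with `records` (raw effect-size records) and `truth`
#'   (the generating means per cell).
#' @export
generate_effect_records <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(sub_seed(config$seed, 2))
  truth <- config$effect_truth
  if (is.null(truth)) truth <- default_effect_truth()
  truth <- tibble::as_tibble(truth)
  stopifnot(all(c("intervention", "climate", "mean") %in% names(truth)))

  k <- config$effect_k
  n_pairs <- config$effect_n_pairs
  bd <- 1400
  depth <- 0.3
  dur <- 20
  metrics <- c("stock_annual", "stock_total", "conc_total")

  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    meas <- names(Filter(function(iv) tr$intervention %in% iv,
                         soc_measure_map))[1]
    sd_annual <- config$effect_cv * max(abs(tr$mean), 1e-3)
    se_annual <- sd_annual / sqrt(n_pairs)
    obs <- rnorm(k, tr$mean, se_annual)
    metric <- metrics[(seq_len(k) - 1) %% length(metrics) + 1]
    value <- ifelse(metric == "stock_annual", obs,
             ifelse(metric == "stock_total", obs * dur,
                    obs * dur / (depth * bd * 0.01)))
    vk <- ifelse(metric == "stock_annual", "SE",
          ifelse(metric == "stock_total", "SD", "CI95"))
    # variation in each record's own reporting units
    v1 <- ifelse(vk == "SE", se_annual,
          ifelse(vk == "SD", sd_annual * dur,
                 value - 1.96 * se_annual * dur / (depth * bd * 0.01)))
    v2 <- ifelse(vk == "CI95",
                 value + 1.96 * se_annual * dur / (depth * bd * 0.01),
                 NA_real_)
    tibble::tibble(
      source_id = sprintf("%s_%s_%02d", tr$intervention, tr$climate,
                          seq_len(k)),
      measure = meas,
      intervention = tr$intervention,
      climate = tr$climate,
      metric = metric,
      value = value,
      variation_kind = vk,
      variation_value = v1,
      variation_value2 = v2,
      n_pairs = n_pairs,
      depth_m = depth,
      duration_yr = dur
    )
  })
  list(records = dplyr::bind_rows(rows), truth = truth)
}

#' Generate synthetic regional manure nitrogen records
#'
#' Regional excretion follows a Dirichlet split of the configured global
#' total; in every region exactly `recycling_fraction` of the excreted N
#' is already applied (split between cropland and grassland), so the
#' aggregate surplus is `(1 - recycling_fraction)` of total excretion.
#'
#' @param config a [generator_config()].
#' @return Tibble (`region_id`, `n_excreted`, `n_applied_cropland`,
#'   `n_applied_grassland`), all kg N yr^-1.
#' @export
generate_manure_records <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(sub_seed(config$seed, 3))
  n <- config$n_regions
  excreted <- rgamma(n, shape = 2, rate = 1)
  excreted <- excreted / sum(excreted) * config$total_excretion_kg
  applied <- config$recycling_fraction * excreted
  crop <- applied * config$cropland_application_share
  tibble::tibble(
    region_id = sprintf("R%02d", seq_len(n)),
    n_excreted = excreted,
    n_applied_cropland = crop,
    n_applied_grassland = applied - crop # splits sum to `applied` exactly
  )
}
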