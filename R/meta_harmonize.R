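# Harmonization of meta-analytical SOC effect sizes into annual stock
# changes (t C ha^-1 yr^-1) with standard errors, and fixed-effect
# inverse-variance pooling per intervention x climate cell.

#' Convert an SOC concentration change to a stock change
#'
#' A concentration change (g C kg^-1 soil) over a soil layer becomes a
#' stock change by multiplying depth (m) by bulk density (kg m^-3) by the
#' concentration change, giving g C m^-2, of which each unit equals
#' 0.01 t C ha^-1.
#'
#' @param delta_conc change in SOC concentration, g C kg^-1; sign preserved.
#' @param bulk_density soil bulk density, kg m^-3; must be positive.
#'   The default 1400 is a representative mineral-topsoil value (global
#'   0-30 cm bulk densities mostly fall in 1200-1600 kg m^-3).
#' @param depth soil layer depth, m; must be positive.
#' @return Stock change in t C ha^-1, vectorised over the inputs.
#' @examples
#' concentration_to_stock(1, 1400, 0.3) # 4.2 t C ha^-1
#' @export
concentration_to_stock <- function(delta_conc, bulk_density = 1400, depth = 0.3) {
  check_number(delta_conc, "delta_conc")
  check_number(bulk_density, "bulk_density", lower = 0, strict = TRUE)
  check_number(depth, "depth", lower = 0, strict = TRUE)
  depth * bulk_density * delta_conc * 0.01
}

#' Normalize a total SOC stock change to an annual rate
#'
#' Divides a cumulative stock change by a reference duration. The default
#' of 20 years is the median duration of the underlying field experiments
#' and assumes linear SOC accumulation over that horizon; standard errors
#' scale by the same factor.
#'
#' @param total_change cumulative stock change, t C ha^-1.
#' @param duration reference duration in years; must be positive.
#' @return Annual stock change, t C ha^-1 yr^-1.
#' @export
annualize <- function(total_change, duration = 20) {
  check_number(total_change, "total_change")
  check_number(duration, "duration", lower = 0, strict = TRUE)
  total_change / duration
}

#' Standard error from a standard deviation and pair count
#'
#' @param sd standard deviation (same units as the mean); non-negative.
#' @param n_pairs number of paired treatment-control comparisons; >= 1.
#' @return `sd / sqrt(n_pairs)`.
#' @export
se_from_sd <- function(sd, n_pairs) {
  check_number(sd, "sd", lower = 0)
  check_number(n_pairs, "n_pairs", lower = 1)
  sd / sqrt(n_pairs)
}

#' Standard error from a 95% confidence interval
#'
#' Assumes a symmetric normal interval, so the standard error is the full
#' interval width divided by 2 * 1.96 = 3.92. Asymmetric intervals are
#' handled the same way (half of the full width per 1.96).
#'
#' @param lower,upper interval endpoints; `upper >= lower`.
#' @return `(upper - lower) / 3.92`.
#' @export
se_from_ci <- function(lower, upper) {
  check_number(lower, "lower")
  check_number(upper, "upper")
  if (any(upper < lower)) stop_invalid("`upper` must be >= `lower`")
  (upper - lower) / 3.92
}

#' Impute a standard deviation from a group-average coefficient of variation
#'
#' Records without any reported measure of variation receive an SD equal to
#' 1.25 times the average coefficient of variation of their management x
#' climate group, times the magnitude of their own mean.
#'
#' @param mean effect-size mean (any sign).
#' @param avg_cv_of_group average CV of the records in the same
#'   intervention x climate group that did report variation; non-negative.
#' @return Imputed SD, `1.25 * avg_cv_of_group * abs(mean)`.
#' @export
impute_sd <- function(mean, avg_cv_of_group) {
  check_number(mean, "mean")
  check_number(avg_cv_of_group, "avg_cv_of_group", lower = 0)
  1.25 * avg_cv_of_group * abs(mean)
}

#' Fixed-effect inverse-variance pooling of annual stock changes
#'
#' Combines estimates for a single intervention x climate cell with weights
#' `w_i = 1 / se_i^2`: the pooled mean is `sum(w * x) / sum(w)` and its
#' standard error `sqrt(1 / sum(w))`. A single record is returned
#' unchanged.
#'
#' @param records data frame with numeric columns `mean` and `se`
#'   (t C ha^-1 yr^-1); all `se` must be strictly positive. If
#'   `intervention` / `climate` columns are present they must be constant.
#' @return One-row tibble with `mean`, `se` and `k_studies` (and the
#'   intervention / climate labels when supplied).
#' @export
pool_effects <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stop_invalid("no records to pool")
  check_number(records$mean, "mean")
  check_number(records$se, "se", lower = 0, strict = TRUE)
  for (key in c("intervention", "climate")) {
    if (key %in% names(records) && length(unique(records[[key]])) > 1) {
      stop_invalid("all records must share the same `%s`", key)
    }
  }
  w <- 1 / records$se^2
  out <- tibble::tibble(
    mean = sum(w * records$mean) / sum(w),
    se = sqrt(1 / sum(w)),
    k_studies = nrow(records)
  )
  for (key in c("intervention", "climate")) {
    if (key %in% names(records)) out[[key]] <- records[[key]][1]
  }
  out[, intersect(c("intervention", "climate", "mean", "se", "k_studies"),
                  names(out))]
}

#' A constant bulk-density provider
#'
#' Bulk density enters only through the concentration-to-stock conversion
#' and is pluggable: any function taking the record table and returning one
#' bulk density (kg m^-3) per row can be used, e.g. a coordinate-keyed
#' lookup. The default provider returns a constant.
#'
#' @param value bulk density in kg m^-3.
#' @return A function `records -> numeric vector`.
#' @export
constant_bd <- function(value = 1400) {
  check_number(value, "value", lower = 0, strict = TRUE)
  function(records) rep(value, nrow(records))
}

validate_effect_records <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("source_id", "measure", "intervention", "climate", "metric",
                "value", "depth_m", "duration_yr")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop_invalid("effect records lack columns: %s",
                 paste(missing_cols, collapse = ", "))
  }
  for (col in c("variation_kind", "variation_value", "variation_value2",
                "n_pairs")) {
    if (!col %in% names(records)) records[[col]] <- NA
  }
  check_enum(records$measure, "measure", soc_measures)
  check_enum(records$intervention, "intervention", soc_interventions)
  check_enum(records$climate, "climate", soc_climates)
  check_enum(records$metric, "metric", soc_metrics)
  check_enum(records$variation_kind[!is.na(records$variation_kind)],
             "variation_kind", c("SD", "SE", "CI95"))
  check_number(records$value, "value")
  check_number(records$depth_m, "depth_m", lower = 0, strict = TRUE)
  # duration is only needed (and must then be positive) for total metrics
  is_total <- records$metric %in% c("stock_total", "conc_total")
  if (any(is_total & (is.na(records$duration_yr) | records$duration_yr <= 0))) {
    stop_invalid("`duration_yr` must be positive for *_total metrics")
  }
  vv <- records$variation_value
  if (any(!is.na(vv) & vv < 0 & records$variation_kind %in% c("SD", "SE"))) {
    stop_invalid("SD/SE variation values must be non-negative")
  }
  ok <- mapply(function(m, i) i %in% soc_measure_map[[m]],
               records$measure, records$intervention)
  if (!all(ok)) {
    stop_invalid("intervention inconsistent with measure in rows: %s",
                 paste(which(!ok), collapse = ", "))
  }
  records
}

# Per-record SD in reporting units, where recoverable; NA otherwise.
reported_sd <- function(records) {
  kind <- records$variation_kind
  n <- records$n_pairs
  v1 <- records$variation_value
  v2 <- records$variation_value2
  se <- ifelse(!is.na(kind) & kind == "SE", v1,
        ifelse(!is.na(kind) & kind == "CI95", (v2 - v1) / 3.92, NA_real_))
  sd <- ifelse(!is.na(kind) & kind == "SD", v1,
        ifelse(!is.na(se) & !is.na(n), se * sqrt(n), NA_real_))
  sd
}

#' Harmonize raw effect-size records into annual stock changes
#'
#' Applies, in order: concentration-to-stock conversion via the
#' bulk-density provider, normalization of cumulative metrics to annual
#' rates over the reference duration, transformation of the reported
#' variation into a standard error (SD/sqrt(n) when an SD and pair count
#' are given, interval width / 3.92 for 95% CIs), and CV-based SD
#' imputation for records reporting no variation. The per-record CV used
#' for imputation is `SD / |mean|` in reporting units; records with mean 0
#' or with no recoverable SD do not contribute to the group-average CV.
#'
#' @param records effect-size record table (see `read_effect_records()` for
#'   the CSV schema).
#' @param bd_provider function mapping the record table to bulk densities
#'   (kg m^-3); default constant 1400.
#' @param ref_duration reference duration (yr) for annualizing `*_total`
#'   metrics; default 20.
#' @param cv_fallback_global if `TRUE`, groups in which no record reports
#'   variation fall back to the global average CV instead of erroring.
#' @return Tibble of annual stock changes with columns `intervention`,
#'   `climate`, `mean`, `se`, `n_pairs` (t C ha^-1 yr^-1).
#' @export
harmonize_records <- function(records, bd_provider = constant_bd(),
                              ref_duration = 20,
                              cv_fallback_global = FALSE) {
  records <- validate_effect_records(records)
  check_number(ref_duration, "ref_duration", lower = 0, strict = TRUE)

  bd <- bd_provider(records)
  check_number(bd, "bulk density", lower = 0, strict = TRUE)

  is_conc <- records$metric %in% c("conc_total", "conc_annual")
  is_total <- records$metric %in% c("stock_total", "conc_total")
  # linear scale taking reporting units to t C ha^-1 yr^-1; applies to the
  # mean and to every measure of variation alike
  scale <- ifelse(is_conc, records$depth_m * bd * 0.01, 1) *
    ifelse(is_total, 1 / ref_duration, 1)

  sd_rep <- reported_sd(records)
  se_rep <- ifelse(!is.na(records$variation_kind) &
                     records$variation_kind == "SE",
                   records$variation_value,
            ifelse(!is.na(records$variation_kind) &
                     records$variation_kind == "CI95",
                   (records$variation_value2 - records$variation_value) / 3.92,
            ifelse(!is.na(sd_rep) & !is.na(records$n_pairs),
                   sd_rep / sqrt(records$n_pairs), NA_real_)))

  cv <- ifelse(!is.na(sd_rep) & records$value != 0,
               abs(sd_rep / records$value), NA_real_)
  group <- paste(records$intervention, records$climate, sep = "|")
  group_cv <- tapply(cv, group, function(x) mean(x, na.rm = TRUE))
  group_cv[is.nan(group_cv)] <- NA_real_
  global_cv <- mean(cv, na.rm = TRUE)

  needs_imp <- is.na(se_rep)
  if (any(needs_imp)) {
    avg_cv <- unname(group_cv[group[needs_imp]])
    if (anyNA(avg_cv)) {
      if (!cv_fallback_global || is.nan(global_cv)) {
        bad <- unique(group[needs_imp][is.na(avg_cv)])
        stop_invalid(
          "cannot impute variation: no reported CV in group(s) %s",
          paste(bad, collapse = "; ")
        )
      }
      avg_cv[is.na(avg_cv)] <- global_cv
    }
    n_imp <- records$n_pairs[needs_imp]
    n_imp[is.na(n_imp)] <- 1
    se_rep[needs_imp] <- impute_sd(records$value[needs_imp], avg_cv) /
      sqrt(n_imp)
  }

  tibble::tibble(
    source_id = records$source_id,
    measure = records$measure,
    intervention = records$intervention,
    climate = records$climate,
    mean = records$value * scale,
    se = se_rep * scale,
    n_pairs = records$n_pairs
  )
}

#' Build the pooled effect table per intervention and climate zone
#'
#' Harmonizes raw records and pools them per intervention x climate with
#' fixed-effect inverse-variance weights. For every intervention an
#' `"other"`-climate cell is added: the inverse-variance combination of the
#' zone-level pooled effects, used as the fallback for zones without their
#' own estimate (records whose own climate label is `"other"` enter that
#' combination as one more cell).
#'
#' @inheritParams harmonize_records
#' @return Tibble with `measure`, `intervention`, `climate`, `mean`, `se`,
#'   `k_studies`, one row per available cell plus the `"other"` row.
#' @export
build_effect_table <- function(records, bd_provider = constant_bd(),
                               ref_duration = 20,
                               cv_fallback_global = FALSE) {
  annual <- harmonize_records(records, bd_provider, ref_duration,
                              cv_fallback_global)
  if (any(annual$se <= 0)) {
    stop_invalid("harmonized records contain non-positive standard errors")
  }
  zone <- annual |>
    dplyr::group_by(.data$measure, .data$intervention, .data$climate) |>
    dplyr::group_modify(~ pool_effects(.x)[, c("mean", "se", "k_studies")]) |>
    dplyr::ungroup()

  # the all-zone cell combines every zone-level pooled effect (a direct
  # "other"-climate cell, when present, enters as one more input cell)
  overall <- zone |>
    dplyr::group_by(.data$measure, .data$intervention) |>
    dplyr::group_modify(function(cells, key) {
      pooled <- pool_effects(cells[, c("mean", "se")])
      pooled$k_studies <- sum(cells$k_studies)
      pooled
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(climate = "other")

  dplyr::bind_rows(zone[zone$climate != "other", ], overall) |>
    dplyr::arrange(.data$measure, .data$intervention,
                   match(.data$climate, soc_climates))
}
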