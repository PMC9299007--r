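# random annual stock-change sets for pooling property tests
random_annual_records <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:8, 1)
  tibble::tibble(
    mean = runif(n, -1, 1),
    se = runif(n, 0.01, 0.5)
  )
}

# independent fixed-effect inverse-variance oracle, written step by step
brute_force_pool <- function(means, ses) {
  w <- numeric(length(means))
  for (i in seq_along(means)) w[i] <- 1 / (ses[i] * ses[i])
  num <- 0
  den <- 0
  for (i in seq_along(means)) {
    num <- num + w[i] * means[i]
    den <- den + w[i]
  }
  list(mean = num / den, se = sqrt(1 / den))
}

# minimal valid effect-size record, overridable per field
make_record <- function(...) {
  base <- tibble::tibble(
    source_id = "s1", measure = "M1", intervention = "IF-NF",
    climate = "temperate", metric = "stock_annual", value = 0.2,
    variation_kind = "SE", variation_value = 0.02,
    variation_value2 = NA_real_, n_pairs = 10, depth_m = 0.3,
    duration_yr = 20
  )
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}

# one toy stratum row, overridable
make_stratum <- function(...) {
  base <- tibble::tibble(
    region_id = "R01", climate = "temperate", fert_class = "medium",
    manure_class = "low", tillage = "HT",
    rotation = "without_catch_crops", residue_fate = "incorporated",
    area_ha = 1e6
  )
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}
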