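test_that("concentration-to-stock conversion follows the depth x BD chain", {
  expect_equal(concentration_to_stock(0, 1400, 0.3), 0)
  expect_equal(concentration_to_stock(1, 1400, 0.3), 4.2)
  expect_equal(concentration_to_stock(2.5, 1200, 0.2), 6.0)
  expect_equal(concentration_to_stock(-1, 1400, 0.3), -4.2) # sign preserved
  expect_error(concentration_to_stock(1, 0, 0.3), "bulk_density")
  expect_error(concentration_to_stock(1, 1400, -0.1), "depth")
})

test_that("conversion matches a step-by-step unit-chain oracle", {
  set.seed(101)
  for (i in 1:1000) {
    conc <- runif(1, -5, 5)       # g C / kg soil
    bd <- runif(1, 900, 1800)     # kg soil / m^3
    depth <- runif(1, 0.1, 1)     # m
    g_per_m2 <- conc * bd * depth # g C / m^2
    t_per_ha <- g_per_m2 * 1e4 / 1e6  # m^2/ha over g/t
    expect_equal(concentration_to_stock(conc, bd, depth), t_per_ha,
                 tolerance = 1e-14)
  }
})

test_that("annualization divides linearly and round-trips", {
  expect_equal(annualize(0, 20), 0)
  expect_equal(annualize(20, 20), 1.0)
  expect_equal(annualize(4.2, 20), 0.21)
  expect_error(annualize(1, 0), "duration")
  set.seed(102)
  for (i in 1:50) {
    x <- runif(1, -3, 3); bd <- runif(1, 1000, 1700)
    d <- runif(1, 0.1, 0.5); dur <- runif(1, 5, 40)
    expect_equal(annualize(concentration_to_stock(x, bd, d), dur) * dur,
                 concentration_to_stock(x, bd, d))
  }
})

test_that("standard errors derive from SD, CI and CV imputation", {
  expect_equal(se_from_sd(0, 10), 0)
  expect_equal(se_from_sd(1, 1), 1)
  expect_equal(se_from_sd(0.4, 16), 0.1)
  expect_error(se_from_sd(0.4, 0), "n_pairs")

  expect_equal(se_from_ci(0.5, 0.5), 0)
  expect_equal(se_from_ci(-0.196, 0.196), 0.1)
  expect_equal(se_from_ci(0.2, 0.6), 0.4 / 3.92)
  expect_error(se_from_ci(0.6, 0.2), "lower")
  # the CI transform inverts a symmetric normal 95% interval exactly
  set.seed(103)
  for (s in c(0, runif(20, 0, 2))) {
    m <- runif(1, -5, 5)
    expect_equal(se_from_ci(m - 1.96 * s, m + 1.96 * s), s,
                 tolerance = 1e-12)
  }

  expect_equal(impute_sd(0, 0.2), 0)
  expect_equal(impute_sd(0.5, 0.2), 0.125)
  expect_equal(impute_sd(-0.4, 0.5), 0.25)
})

test_that("inverse-variance pooling matches hand-computed weights", {
  one <- pool_effects(tibble::tibble(mean = 0.21, se = 0.02))
  expect_equal(one$mean, 0.21)
  expect_equal(one$se, 0.02)
  expect_equal(one$k_studies, 1)

  sym <- pool_effects(tibble::tibble(mean = c(0.1, 0.3), se = 0.05))
  expect_equal(sym$mean, 0.2)

  # weights 1/0.01^2 = 10000 and 1/0.02^2 = 2500
  two <- pool_effects(tibble::tibble(mean = c(0.12, 0.17),
                                     se = c(0.01, 0.02)))
  expect_equal(two$mean, (0.12 * 10000 + 0.17 * 2500) / 12500)
  expect_equal(two$mean, 0.13)
  expect_equal(two$se, sqrt(1 / 12500))
  expect_equal(two$se, 0.008944272, tolerance = 1e-6)

  expect_error(pool_effects(tibble::tibble(mean = numeric(), se = numeric())),
               "no records")
  expect_error(pool_effects(tibble::tibble(mean = 0.1, se = 0)), "se")
  expect_error(pool_effects(tibble::tibble(
    mean = c(0.1, 0.2), se = 0.1, intervention = c("IF-NF", "CC")
  )), "intervention")
})

test_that("pooling is convex, precision-increasing, permutation-invariant and scale-equivariant", {
  set.seed(104)
  for (i in 1:200) {
    rec <- random_annual_records()
    pooled <- pool_effects(rec)
    expect_gte(pooled$mean, min(rec$mean) - 1e-12)
    expect_lte(pooled$mean, max(rec$mean) + 1e-12)
    expect_lte(pooled$se, min(rec$se) + 1e-12)

    perm <- pool_effects(rec[sample(nrow(rec)), ])
    expect_equal(perm$mean, pooled$mean)
    expect_equal(perm$se, pooled$se)

    c_scale <- runif(1, 0.1, 10)
    scaled <- pool_effects(tibble::tibble(mean = rec$mean * c_scale,
                                          se = rec$se * c_scale))
    expect_equal(scaled$mean, pooled$mean * c_scale)
    expect_equal(scaled$se, pooled$se * c_scale)
  }
})

test_that("pooling agrees with an established fixed-effect meta-analysis fit", {
  skip_if_not_installed("metafor")
  set.seed(105)
  for (i in 1:20) {
    rec <- random_annual_records(sample(2:10, 1))
    fit <- metafor::rma(yi = rec$mean, sei = rec$se, method = "FE")
    pooled <- pool_effects(rec)
    expect_equal(pooled$mean, as.numeric(fit$beta), tolerance = 1e-10)
    expect_equal(pooled$se, as.numeric(fit$se), tolerance = 1e-10)
  }
})

test_that("harmonization converts mixed metrics to one annual stock scale", {
  # four reporting routes of the same underlying 0.21 t C ha^-1 yr^-1
  recs <- dplyr::bind_rows(
    make_record(source_id = "a", metric = "stock_annual", value = 0.21,
                variation_kind = "SE", variation_value = 0.02),
    make_record(source_id = "b", metric = "stock_total", value = 4.2,
                variation_kind = "SD", variation_value = 0.4 * 20,
                n_pairs = 16),
    make_record(source_id = "c", metric = "conc_total", value = 1,
                variation_kind = "CI95",
                variation_value = 1 - 1.96 * 0.1,
                variation_value2 = 1 + 1.96 * 0.1),
    make_record(source_id = "d", metric = "conc_annual", value = 0.05,
                variation_kind = "SE", variation_value = 0.005)
  )
  out <- harmonize_records(recs) # constant BD 1400, depth 0.3, T = 20
  expect_equal(out$mean, c(0.21, 0.21, 0.21, 0.21))
  expect_equal(out$se[1], 0.02)
  expect_equal(out$se[2], 0.4 * 20 / 4 / 20) # SD/sqrt(n), then annualized
  expect_equal(out$se[3], 2 * 1.96 * 0.1 / 3.92 * 4.2 / 20)
  expect_equal(out$se[4], 0.005 * 4.2)
})

test_that("missing variation is imputed from the group CV, with errors otherwise", {
  recs <- dplyr::bind_rows(
    make_record(source_id = "a", value = 0.2, variation_kind = "SD",
                variation_value = 0.1, n_pairs = 4), # CV = 0.5
    make_record(source_id = "b", value = 0.4, variation_kind = NA_character_,
                variation_value = NA_real_, n_pairs = 4)
  )
  out <- harmonize_records(recs)
  # SD = 1.25 * 0.5 * 0.4 = 0.25, SE = 0.25 / 2
  expect_equal(out$se[2], 0.125)

  # no reported variation anywhere in the group -> imputation unavailable
  lonely <- dplyr::bind_rows(
    make_record(source_id = "a", value = 0.2, variation_kind = NA_character_,
                variation_value = NA_real_, n_pairs = NA_integer_),
    make_record(source_id = "b", value = 0.3, climate = "tropical",
                variation_kind = "SD", variation_value = 0.06, n_pairs = 9)
  )
  expect_error(harmonize_records(lonely), "impute")
  fallback <- harmonize_records(lonely, cv_fallback_global = TRUE)
  expect_equal(fallback$se[1], 1.25 * 0.2 * 0.2 / 1) # global CV = 0.2, n = 1

  # a record with mean zero must not poison the group CV
  with_zero <- dplyr::bind_rows(
    make_record(source_id = "a", value = 0, variation_kind = "SD",
                variation_value = 0.1, n_pairs = 4),
    make_record(source_id = "b", value = 0.2, variation_kind = "SD",
                variation_value = 0.1, n_pairs = 4),
    make_record(source_id = "c", value = 0.4, variation_kind = NA_character_,
                variation_value = NA_real_, n_pairs = 4)
  )
  out0 <- harmonize_records(with_zero)
  expect_equal(out0$se[3], 1.25 * 0.5 * 0.4 / 2)
})

test_that("record validation enforces the domain invariants", {
  expect_error(harmonize_records(make_record(depth_m = 0)), "depth")
  expect_error(harmonize_records(make_record(metric = "stock_total",
                                             duration_yr = NA)),
               "duration")
  expect_error(harmonize_records(make_record(intervention = "CRES")),
               "inconsistent")
  expect_error(harmonize_records(make_record(climate = "boreal")), "climate")
})

test_that("the effect table pools per cell and adds an all-zone entry", {
  # single record, single zone: passthrough into both cells
  single <- build_effect_table(make_record())
  expect_equal(nrow(single), 2)
  expect_equal(single$mean, c(0.2, 0.2))
  expect_equal(single$climate, c("temperate", "other"))

  # two zones with equal se: the all-zone cell is the arithmetic mean
  two <- build_effect_table(dplyr::bind_rows(
    make_record(source_id = "a", value = 0.1),
    make_record(source_id = "b", value = 0.3, climate = "tropical")
  ))
  expect_equal(two$mean[two$climate == "other"], 0.2)
  expect_equal(two$se[two$climate == "other"], 0.02 / sqrt(2))

  # feeding the packaged pooled cells back as single annual records
  # reproduces the zone cells verbatim
  fix <- soc_effect_table()
  zones <- fix[fix$climate != "other", ]
  recs <- tibble::tibble(
    source_id = paste0("fx", seq_len(nrow(zones))),
    measure = zones$measure, intervention = zones$intervention,
    climate = zones$climate, metric = "stock_annual", value = zones$mean,
    variation_kind = "SE", variation_value = zones$se,
    variation_value2 = NA_real_, n_pairs = NA_integer_,
    depth_m = 0.3, duration_yr = 20
  )
  tab <- build_effect_table(recs)
  got <- dplyr::inner_join(
    zones, tab, by = c("measure", "intervention", "climate")
  )
  expect_equal(nrow(got), nrow(zones))
  expect_equal(got$mean.y, got$mean.x)
  expect_equal(got$se.y, got$se.x)
})
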