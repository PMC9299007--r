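flat_effects <- function(mean = 0.23, se = 0.02, intervention = "NT-HT") {
  tibble::tibble(
    intervention = intervention,
    climate = c("temperate", "subtropical", "tropical", "other"),
    mean = mean, se = se
  )
}

one_area <- function(area_ha = 100e6, climate = "temperate",
                     intervention = "NT-HT") {
  tibble::tibble(climate = climate, intervention = intervention,
                 area_ha = area_ha)
}

test_that("potentials are area times effect, summed per zone", {
  expect_equal(measure_potential(one_area(0), flat_effects())$potential_mton,
               0)
  # 100 Mha at 0.23 t C/ha/yr = 23 Mton C/yr
  expect_equal(measure_potential(one_area(), flat_effects())$potential_mton,
               23)
  two <- dplyr::bind_rows(one_area(40e6), one_area(60e6))
  expect_equal(measure_potential(two, flat_effects())$potential_mton, 23)

  # linear in area and in effect size
  set.seed(401)
  for (i in 1:20) {
    a <- runif(1, 1e6, 1e9); e <- runif(1, -0.5, 0.5); k <- runif(1, 0.5, 4)
    base <- measure_potential(one_area(a),
                              flat_effects(mean = e))$potential_mton
    expect_equal(measure_potential(one_area(a * k),
                                   flat_effects(mean = e))$potential_mton,
                 base * k)
    expect_equal(measure_potential(one_area(a),
                                   flat_effects(mean = e * k))$potential_mton,
                 base * k, tolerance = 1e-12)
  }
})

test_that("zones without their own effect fall back to the all-zone cell", {
  eff <- tibble::tibble(intervention = "CRES",
                        climate = c("temperate", "other"),
                        mean = c(0.21, 0.15), se = 0.02)
  area <- one_area(100e6, climate = "tropical", intervention = "CRES")
  expect_equal(measure_potential(area, eff)$potential_mton, 15)
  expect_error(measure_potential(area, eff[1, ]), "no effect size")
  expect_error(measure_potential(area, eff[1, ], fallback_other = FALSE),
               "no effect size")
})

test_that("Monte-Carlo bounds collapse to the mean at zero variance and are reproducible", {
  mc0 <- monte_carlo_potential(one_area(), flat_effects(se = 0),
                               n_mc = 100, seed = 1)
  expect_equal(mc0$q01, mc0$q99)
  expect_equal(mc0$q01[mc0$climate == "temperate"], 23)

  a <- monte_carlo_potential(one_area(), flat_effects(), n_mc = 500,
                             seed = 99, retain_draws = TRUE)
  b <- monte_carlo_potential(one_area(), flat_effects(), n_mc = 500,
                             seed = 99, retain_draws = TRUE)
  expect_identical(a, b)
  expect_equal(dim(attr(a, "draws")), c(500, 2))

  expect_error(monte_carlo_potential(one_area(), flat_effects(), n_mc = 1),
               "n_mc")
})

test_that("Monte-Carlo quantiles track the analytic normal quantiles", {
  # one cell, 1 Gha at 0.1 +/- 0.01 -> potential ~ Normal(100, 10) Mton
  mc <- monte_carlo_potential(
    one_area(1e9), flat_effects(mean = 0.1, se = 0.01),
    n_mc = 20000, seed = 5
  )
  z <- stats::qnorm(c(0.01, 0.99))
  row <- mc[mc$climate == "temperate", ]
  expect_equal(row$q01, 100 + z[1] * 10, tolerance = 0.02)
  expect_equal(row$q99, 100 + z[2] * 10, tolerance = 0.02)
})

test_that("scenario totals reproduce the published aggregation arithmetic", {
  glob <- soc_global_potentials()

  maxc <- combine_max_complementarity(glob)
  expect_equal(maxc$total, 561)
  expect_equal(maxc$low, 440)
  expect_equal(maxc$high, 683)

  ranked <- combine_rank_weighted(glob)
  expect_equal(ranked$ranks, c("M3", "M4", "M1", "M5", "M2"))
  expect_equal(unname(ranked$weights), 1 / (1:5))
  expect_equal(ranked$total, 227 + 153 / 2 + 78 / 3 + 73 / 4 + 30 / 5)
  expect_equal(round(ranked$total), 354)
  expect_equal(round(ranked$low), 278)
  expect_equal(round(ranked$high), 432)
  expect_lte(ranked$total, maxc$total)
  expect_gte(ranked$total, max(glob$potential_mton))

  zeros <- tibble::tibble(measure = soc_measures, potential_mton = 0,
                          q01 = 0, q99 = 0)
  expect_equal(combine_max_complementarity(zeros)$total, 0)

  single <- zeros
  single$potential_mton[3] <- 42
  single$q01[3] <- 40
  single$q99[3] <- 44
  expect_equal(combine_rank_weighted(single)$total, 42)

  expect_error(combine_rank_weighted(glob[1:4, ]), "five measures")
  dup <- glob
  dup$measure[2] <- "M1"
  expect_error(combine_max_complementarity(dup), "five measures")
})

test_that("published zone potentials add up to every measure's global value", {
  tab <- soc_potential_table()
  zones <- tab[tab$climate != "all", ]
  alls <- tab[tab$climate == "all", ]
  sums <- tapply(zones$potential_mton, zones$measure, sum)
  expect_equal(as.numeric(sums[alls$measure]), alls$potential_mton)
})
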