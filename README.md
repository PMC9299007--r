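# socpotential

Estimation of the global soil organic carbon (SOC) sequestration
potential of improved cropland management, built as a reusable R
pipeline over four stages:

1. **Meta-analysis harmonization** — SOC effect sizes reported by
   meta-studies in mixed metrics (cumulative or annual stocks,
   concentrations; SD, SE or 95% CI) are converted to annual stock
   changes in t C ha⁻¹ yr⁻¹ (concentration × bulk density × depth ×
   0.01; cumulative changes divided by a 20-yr reference duration) and
   pooled per management intervention × climate zone with fixed-effect
   inverse-variance weights *wᵢ = 1/SEᵢ²*:
   *x̄ = Σwᵢxᵢ/Σwᵢ*, *SE(x̄) = √(1/Σwᵢ)*.
2. **Stratification** — cropland area is classified by current
   management (inorganic-N classes at 40 and 100 kg N ha⁻¹ yr⁻¹,
   manure at 40; tillage NT/IT/HT; rotations with/without catch crops;
   residue incorporated/burned/removed), and each measure's eligible
   area is the complement of its current extent.
3. **Manure budget** — additional organic fertilization is capped per
   region by the stable carbon in not-yet-recycled manure:
   *C = max(0, N_excreted − N_applied) × C:N × h* with C:N = 10 and
   humification coefficient h = 0.5.
4. **Upscaling** — potential = Σ area × effect (Mton C yr⁻¹) per
   measure and climate zone; uncertainty propagated by Monte Carlo
   (n = 1000, normal draws per effect cell, 0.01/0.99 quantiles);
   measures combined assuming full additivity or 1/rank-declining
   weights.

The five measures are M1 increased inorganic fertilization, M2
increased organic inputs (M2cor once capped by the manure budget), M3
reduced tillage, M4 increased crop diversity, M5 crop residue
incorporation. A seeded synthetic-data generator reproduces the
marginal composition of the global cropland layers (climate 30/19/30/21
%, 45 % high-intensity tillage, 8 % no-till, 25 % residue burning, 72 %
rotations without catch crops, 1,416,912 kha total, 129 Tg manure-N
excretion with ≥ 90 % recycled) so the full pipeline runs and is tested
without any spatial downloads. See `vignettes/upscaling-methods.Rmd`
for the model, assumptions and design decisions.

## Worked example

Combine the packaged per-measure potentials (Mton C yr⁻¹, manure-capped
organic fertilization) into the two scenario totals:

```r
library(socpotential)
glob <- soc_global_potentials()
glob
#> # A tibble: 5 × 4
#>   measure potential_mton   q01   q99
#>   <chr>            <dbl> <dbl> <dbl>
#> 1 M1                  78    70    88
#> 2 M2                  30    26    30
#> 3 M3                 227   182   273
#> 4 M4                 153   106   202
#> 5 M5                  73    56    90
combine_max_complementarity(glob)
#> Scenario (max_complementarity): 561 Mton C yr^-1 [440, 683]
#>   ranks: M3 > M4 > M1 > M5 > M2
#>   weights: M1=1.00, M2=1.00, M3=1.00, M4=1.00, M5=1.00
combine_rank_weighted(glob)
#> Scenario (rank_weighted): 354 Mton C yr^-1 [278, 432]
#>   ranks: M3 > M4 > M1 > M5 > M2
#>   weights: M3=1.00, M4=0.50, M1=0.33, M5=0.25, M2=0.20
```

Under full additivity the five measures could sequester 561 Mton C yr⁻¹
(bounds 440–683); under the more conservative 1/rank weighting — the
k-th strongest measure contributes 1/k of its value — the total is
354 Mton C yr⁻¹ (278–432). Reduced tillage (M3) dominates because its
eligible area is huge, while organic fertilization collapses from 592 to
30 Mton C yr⁻¹ once capped by the < 10 % of manure carbon not already
recycled.

The analysis workflow runs the same chain on synthetic inputs:

```sh
Rscript analysis/01_simulate.R        # cells, effect records, manure regions
Rscript analysis/02_harmonize.R       # pooled effect table vs generator truth
Rscript analysis/03_classify_strata.R # strata, shares, eligible areas
Rscript analysis/04_manure_budget.R   # 12.9 Tg N surplus -> 64.5 Mton stable C
Rscript analysis/05_upscale.R         # per-measure potentials with MC bounds
Rscript analysis/06_scenarios.R       # published + simulated scenario totals
```

Each script prints what it found and writes its tables under
`results/`; e.g. `04_manure_budget.R` reports

```
total excretion: 129.0 Tg N/yr
unrecycled surplus: 12.9 Tg N/yr (10% of excretion)
stable C supply: 64.5 Mton C/yr across 20 regions
```

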