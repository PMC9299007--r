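---
title: "Methods: from meta-analytical SOC effect sizes to global sequestration potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from meta-analytical SOC effect sizes to global sequestration potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socpotential)
```

## The estimation problem

Improved cropland management — more balanced fertilization, organic
inputs, reduced tillage, diversified rotations, residue incorporation —
can rebuild depleted soil organic carbon (SOC) stocks. Published
meta-analyses report the per-hectare SOC response of each practice, but a
global potential requires two more ingredients: the area where each
practice can still be adopted (its potential is zero where it is already
applied), and a resource constraint for practices that move carbon around
rather than add it (manure applied on one field is carbon taken from
another). This package implements that estimation chain in four stages,
each usable on its own:

1. **Harmonization and pooling** (`harmonize_records()`,
   `pool_effects()`, `build_effect_table()`): meta-study effect sizes in
   heterogeneous metrics become annual stock changes
   (t C ha^-1 yr^-1) with standard errors, pooled per management
   intervention and climate zone.
2. **Stratification** (`classify_cells()`, `eligible_area()`): cropland
   area is classified by current management, and the complement of each
   practice's current extent gives the area where it can still be
   adopted.
3. **Manure budget** (`recyclable_manure_c()`,
   `cap_measure_potential()`): the organic-fertilization potential is
   capped by the regional supply of manure carbon not yet recycled.
4. **Upscaling** (`measure_potential()`, `monte_carlo_potential()`,
   `combine_*()`): area times effect, summed per zone, with Monte-Carlo
   uncertainty propagation and two complementarity scenarios.

## Harmonization model

Effect sizes arrive as raw mean differences between treatment and
control, expressed as stocks (t C ha^-1, cumulative or annual) or
concentrations (g C kg^-1). Two linear conversions put everything on one
scale:

* **Concentration to stock.** A concentration change over a layer of
  depth $d$ (m) with bulk density $\rho$ (kg m^-3) is
  $\Delta SOC_{stock} = d \, \rho \, \Delta SOC_{conc} \times 0.01$
  t C ha^-1 (each g C m^-2 is 0.01 t C ha^-1). Bulk density is a
  pluggable provider; the default is a constant 1400 kg m^-3, a
  representative mineral-topsoil value (the global 0–30 cm range is
  roughly 1200–1600). A coordinate-keyed provider can be substituted
  when study locations are known.
* **Cumulative to annual.** Cumulative changes are divided by a
  reference duration of 20 years — the median duration of the underlying
  experiments — assuming linear accumulation over that horizon. This
  understates short-term and overstates long-term responses; SOC
  accumulation is in reality a saturating process, so the annual rates
  should be read as medium-term averages. The per-study duration is
  validated and retained but deliberately not used as the divisor, so
  that all measures are compared over the same horizon; `annualize()`
  accepts any duration for sensitivity work.

Variation is converted to a standard error in this priority order: a
reported SD with pair count gives $SE = SD/\sqrt{n}$ (first even when a
CI is also reported); a reported 95% CI gives $SE = width/3.92$,
treating the interval as symmetric normal (asymmetric intervals use half
the full width; no log-scale back-transform is attempted because raw
mean differences, not ratios, are pooled). Records reporting no
variation receive an imputed SD of 1.25 times the average coefficient of
variation of their intervention × climate group times their own mean
magnitude — a deliberately pessimistic inflation so that unreported
variation never gains weight. The per-record CV is $SD/|mean|$ in
reporting units; records with mean zero or no recoverable SD are
excluded from the group average, and a group with no reported variation
at all raises an error unless the global-average fallback is enabled.
Imputed records lacking a pair count are treated as $n = 1$ (SD = SE),
the most conservative choice.

### Pooling

Cells are pooled with fixed-effect inverse-variance weights
$w_i = 1/SE_i^2$:

$$\bar{x} = \frac{\sum w_i x_i}{\sum w_i}, \qquad
  SE(\bar{x}) = \sqrt{\frac{1}{\sum w_i}}.$$

The pooled mean always lies in the convex hull of its inputs and the
pooled SE never exceeds the smallest input SE; both are asserted as
properties in the test suite, and the implementation is cross-checked
against an independent fixed-effect meta-analysis fit (`metafor`). A
fixed-effect (not random-effects) model is the intended aggregation
here: the inputs are themselves meta-analytic summaries, and
between-study heterogeneity cannot be separated from the unknown overlap
of primary experiments across meta-studies. That overlap also means the
pooled SEs are likely underestimates; no inflation factor is applied
because overlap counts are unavailable.

For every intervention an all-zone cell (labelled `"other"`) is computed
as the inverse-variance combination of the zone-level pooled effects and
used as the fallback wherever a climate zone lacks its own estimate
(tropical tillage data, notably, are too sparse for a zone-specific
estimate). The packaged reference effect table (`soc_effect_table()`)
ships its published all-zone values verbatim rather than recomputing
them, because the published combination was evidently done at the study
level, which the printed (rounded) zone cells cannot reproduce exactly;
the recomputation path is therefore validated on synthetic data.

## Stratification

Cropland cells carry climate zone, area, inorganic-N and manure-N
application rates, tillage class, rotation class and residue fate.
Classification thresholds:

| attribute | classes | cut-offs (kg N ha^-1 yr^-1) |
|---|---|---|
| inorganic N | none / medium / high | `[0, 40)` / `[40, 100]` / `(100, ∞)` |
| manure N | low / high | `[0, 40)` / `[40, ∞)` |

The 40 kg N ha^-1 bound for "unfertilized" is the headline threshold;
the 100 kg N ha^-1 medium/high bound is adopted from the narrative range
("between 40 and 100 kg N ha^-1 from inorganic fertilizers" on most
land), with lower class edges inclusive. Eligibility per measure: M1
applies inorganic fertilization to unfertilized strata (`IF-NF`); M2
applies organic fertilization to unfertilized strata (`OF-NF`) and
substitutes it on fertilized low-manure strata (`OF-IF`), leaving
high-manure strata ineligible; M3 converts high-intensity and
intermediate tillage to no-till (`NT-HT`, `NT-IT`); M4 adds catch crops
to rotations without them (`CC`); M5 incorporates residues where they
are currently burned *or* removed (`CRES`) — burning and removal are
treated alike because both currently return no residue carbon to the
soil. The combined-fertilization contrasts (`COF-NF`, `CRF-NF`) are kept
in the effect table but not area-mapped by default: mapping them would
double-count area already assigned to `OF-*`. Classification is a
partition (every cell lands in exactly one stratum; total area is
conserved to machine precision) and eligible area is monotone in added
cells — both are property-tested.

## Manure budget

Let $N_{ex}$ be the N excreted by livestock in a region and $N_{ap}$ the
N already applied on cropland and grassland (including grazing
deposition). The recyclable stable carbon supply is

$$C_{stable} = \max(0,\; N_{ex} - N_{ap}) \times C{:}N \times h$$

with C:N = 10 (midpoint of slurry ≈ 8 and solid manure ≈ 15, overridable
and worth a 8–15 sensitivity sweep) and humification coefficient
$h = 0.5$, the fraction of applied organic carbon not decomposed within
one year (literature range roughly 0.3–0.75). Manure burned as fuel
counts as unapplied surplus. The cap is applied **per region** before
zone aggregation — a surplus in one country cannot fertilize another —
and under uncertainty it is applied inside every Monte-Carlo draw, so a
draw in which the raw potential falls below the budget is not clipped.
With excretion calibrated to 129 Tg N yr^-1 and 90% recycling, the
surplus is 12.9 Tg N yr^-1 and the stable-C supply 64.5 Mton C yr^-1;
the binding cap is what pulls the organic-fertilization measure down by
an order of magnitude, the pipeline's most consequential correction.

## Upscaling and uncertainty

The deterministic potential of a measure in a zone is
$P = \sum_{strata} A \cdot \Delta SOC \times 10^{-6}$ Mton C yr^-1 with
$A$ in ha. Uncertainty comes from the pooled effect sizes: each of
$n_{mc} = 1000$ draws samples every effect cell independently from
$\mathcal{N}(mean, SE)$ (no cross-cell correlation structure is imposed
— none is identifiable from the inputs) and recomputes the potentials.
Reported bounds are the 0.01 and 0.99 quantiles of the draws, estimated
by linear interpolation of order statistics (`quantile()` type 7). The
zone draws are generated once and summed within draws for the `"all"`
row, so measure-level totals are quantiles of sums; scenario-level
bounds, by contrast, are **sums of per-measure quantiles**, which is the
published aggregation arithmetic and is slightly wider than the quantile
of the summed draws. Both conventions are computable; the sum-of-bounds
one is the reported default at scenario level. All draws flow from one
seed (sub-streams per measure), so a rerun with the same configuration
is byte-identical.

Two scenario rules combine the five measures (with organic fertilization
entering as its manure-capped version):

* **Maximum complementarity** — plain sums: totals 561 Mton C yr^-1 with
  bounds 440–683 from the packaged potential table.
* **Rank-declining weights** — measures sorted by mean potential, the
  k-th contributing $1/k$ of its value (ties broken by measure label):
  354 with bounds 278–432. The $1/k$ scheme is the only simple declining
  scheme (against $2^{-k+1}$ and linear decline) that reproduces all
  three published totals; the test suite fixes it by that arithmetic.
  The same mean-derived ranks are applied to the bounds so that the rule
  stays a deterministic function of the mean ordering.

Totals are reported in Mton C yr^-1 rounded to integers; tests compare
rounded totals within ±1 Mton.

## The synthetic generator

Real inputs are continental raster/statistical layers (crop allocation,
climate classification, tillage, fertilizer and manure rates, residue
statistics). The generator reproduces their *marginal* statistical
structure so every stage is exercised without downloads: configurable
area shares per climate (30/19/30/21% tropical/temperate/subtropical/
other), tillage (45% HT, 8% NT), residue burning (25%), rotations
without catch crops (72%), and a joint fertilizer × manure draw hitting
13% of area in the high–high class. N rates are drawn from
class-truncated lognormals so the induced classes match the categorical
draw exactly; cell areas follow a symmetric Dirichlet rescaled to a
total of 1,416,912 kha exactly. Defaults chosen where the global
marginals end: fertilization class shares none/medium/high =
0.25/0.50/0.25 (consistent with "most land between 40 and 100 kg N"),
manure-high probability 0.10 outside the high-fertilization class, and
residue remainder split 60% incorporated / 15% removed. Effect records
are drawn around a stored truth table (by default the packaged pooled
means) cycling through the three reporting routes — annual stock with
SE, cumulative stock with SD and n, cumulative concentration with a 95%
CI — constructed to harmonize back to the same truth, which makes
parameter recovery through the full conversion chain testable. Manure
regions split a configurable excretion total with an exact recycling
fraction.

What the generator does **not** emulate: spatial autocorrelation, real
country borders and bilateral trade in feed or manure, correlations
between climate and management intensity, or crop-specific
disaggregation. Passing tests on synthetic data therefore validate the
computational chain and its statistical calibration, not the realism of
any particular global number; the published-table fixture is what ties
the arithmetic to the real analysis.

## Numerical choices and degenerate inputs

* Zero-SE records are rejected by pooling (they would carry infinite
  weight); the all-zero-SE Monte-Carlo case degenerates cleanly to the
  deterministic potential.
* A zero mean yields an undefined CV and is excluded from imputation
  averages; an imputed SD of zero (zero mean) survives harmonization but
  is rejected at pooling, which is the right failure point.
* Classification boundaries are lower-edge-inclusive; rates are
  validated non-negative.
* The nitrogen surplus clamps at zero per region; clamping is why budget
  aggregation is additive only across non-clamped regions, and why the
  cap must be applied at the region level.
* Areas, rates and budgets are carried in base units (ha, kg) and
  converted once at the reporting boundary (Mton = 10^9 kg).

## Problem sizes

The test suite runs the generator at up to 10^4 cells (marginal-share
checks), pools 10^3 random record sets against a brute-force oracle,
calibrates the Monte-Carlo quantiles on a one-cell problem at 10^5
draws against analytic normal quantiles (±2.326 SD within 1%), and runs
the end-to-end pipeline at a few hundred cells with reduced draw counts.
The analysis scripts use 10^4 cells and 10^3 draws, matching the
published Monte-Carlo size.

## Known limitations

* Fixed-effect pooling of overlapping meta-studies underestimates SEs;
  no overlap correction is possible without primary-study identities.
* The 20-year linear assumption ignores saturation; potentials are not
  valid beyond the medium term, and the humification-based manure cap is
  itself optimistic (one-year stable fraction, assuming sustained
  application).
* Equivalent-soil-mass corrections for tillage-induced bulk-density
  change are not applied.
* Measure interactions (synergy or antagonism under combined adoption)
  are not modelled; the two scenario rules bracket, not resolve, that
  uncertainty.
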