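---
title: "Methods: from land-use change to smoke exposure and health burden"
author: "smokeburden authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from land-use change to smoke exposure and health burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokeburden)
```

# The model chain and its assumptions

`smokeburden` estimates the public-health consequences of land-management
decisions in a fire-prone region. The chain is: land-use and land-cover
(LULC) change determines where and how much biomass burns; burning emits
organic and black carbon (OC + BC), the primary constituents of smoke
PM2.5; atmospheric transport, summarized by precomputed adjoint sensitivity
fields, maps emissions to receptor population-weighted concentrations; and
concentration-response functions (CRFs) convert exposure differences to
attributable deaths. Three assumptions carry the whole construction:

* **Linearity of transport.** Receptor exposure is a dot product of a
  nonnegative sensitivity field with the emission flux. This is what makes
  scenario differencing, mask dominance (blocking fires can only reduce
  every receptor metric) and exact additivity of nonoverlapping site
  benefits true by construction, and it is why greedy top-k site selection
  is provably optimal. Secondary aerosol chemistry, which is nonlinear, is
  excluded; the fields describe primary OC/BC only.
* **Stationarity of learned rates.** Emission rates per coarse cell,
  attribution stratum and calendar month are climatological means over the
  observation years and are assumed to hold in the future; interannual
  meteorology re-enters through the repeating met-year schedule applied to
  the sensitivity fields, not through the rates.
* **Fixed demography.** Population counts and baseline mortality rates are
  held constant over the projection; attributable-death errors scale
  proportionally with the at-risk population.

# Stage by stage

## Land-use change (weights of evidence)

Four cover classes (intact primary forest, degraded primary forest,
tree plantation / secondary forest, nonforest) carry an immutable peat
flag. `merge_layers()` builds the classification from a 3-class forest map,
a binary tree-cover layer (splitting nonforest into plantation/secondary
vs. open land) and a peat mask.

`calibrate_woe()` learns, for every observed transition, binned positive
weights of evidence over the eligible (source-class) cells, and
`project_lulc()` converts exactly the demanded number of cells per 5-year
step, ranked by `logit(prior) + Σ W⁺`. Choices made here, where the
standard cellular-simulation toolchain leaves them open:

* evidence layers are binned by **deciles** over eligible cells
  (configurable); additive **+0.5 smoothing** in every bin keeps weights
  finite in empty bins;
* **demand defaults to the calibration-period observed counts** — the
  business-as-usual reading "observed trends continue" — and can be
  overridden per transition;
* the **patcher/expander patch-geometry machinery** of cellular land-change
  simulators is omitted deliberately: downstream emissions are integrated
  over coarse cells, so patch shape cannot affect them at that resolution;
* ties in the probability surface are broken by a **seeded uniform draw
  made once per step**, which makes selections nested in demand under a
  fixed seed;
* dynamic distance-to-class layers are recomputed every step with a
  two-pass 3–4 chamfer transform (cell units);
* WoE's additive log-odds combination assumes conditional independence of
  the layers; `check_vif()` screens covariates at the conventional VIF < 5
  and the package only warns beyond that — responsibility for the layer set
  stays with the analyst.

## Emissions

`downscale()` shares coarse cell-month mass among nested fine cells in
proportion to FRP. Where a coarse cell-month has emissions but no FRP
detection, mass is distributed by the area ratio of land-cover strata,
uniformly by area within a stratum; with no per-stratum weighting supplied
this degenerates to area-proportional sharing (the two formulations are
algebraically identical in that case), and an optional per-stratum weight
argument restores the distinction when wanted. Exact nesting of the fine
grid into the coarse grid is required by construction, so no area-weight
interpolation ever occurs, and per-coarse-cell monthly totals are conserved
to machine precision.

`estimate_scaling_factors()` learns `rate(c, T, m)` as the multi-year mean
of stratum emissions over stratum area. All months enter the mean,
including fire-free ones — rates are per calendar month, so zeros are
information, not missingness. Strata absent from a coarse cell get *no
entry*, distinct from a zero rate; projection treats future strata without
a learned rate as zero with a warning. Repeated burning at a location is
handled by the mean itself. `speciate()` applies per-fire-type emission
factors (g species / kg DM, divided by 1000 for the kg/kg bookkeeping);
the default table (peat 6.02/0.04, deforestation 4.71/0.52, agricultural
2.30/0.75 g/kg OC/BC) is configuration data, not code.

## Exposure

`to_flux()` divides cell-month mass by cell area (m²) and seconds in the
month — sub-monthly fire timing is deliberately collapsed, consistent with
monthly mean sensitivity maps. `build_schedule()` cycles the available
meteorological years (`(y − start) mod n`), and `apply_sensitivities()`
contracts. Population weighting lives inside the sensitivity fields, as it
does in an adjoint cost function; exposure code never touches population
rasters. OC and BC are summed before contraction.

## Health

The adult all-cause CRF is linear: 1.03% risk increase per µg/m³ annual
PM2.5 (95% CI 0.97–1.11%). The child (<5) ALRI CRF is 1.2% per µg/m³
(CI 0.3–3.0%/µg/m³, i.e. 3–30% per 10 µg/m³) up to a 50 µg/m³ breakpoint.
Above the breakpoint the risk curve continues log-linearly; the exact
parametric continuation is not pinned down by the sources the slopes come
from, so this package uses the continuity construction

$$\Delta R(C) = (1 + sB)\,e^{k(C-B)} - 1, \qquad k = \frac{s}{1+sB},$$

which is the unique exponential continuation that is both value- and
slope-continuous at the breakpoint $B$. It is a declared design choice,
flagged for sensitivity analysis; each CI bound uses its own slope in the
same construction, which preserves the low ≤ central ≤ high ordering for
all concentrations.

Two further decisions in `burden_table()` are configurable because the
sources leave them open:

* **Exposure basis.** CRFs are annual, but smoke exposure is reported for
  Jul–Oct. The default converts to an annual mean (burning-season exposure
  diluted over 12 months) before applying the CRF;
  `exposure_basis = "seasonal"` treats the Jul–Oct mean as the annual
  concentration instead. The default is the conservative reading.
* **Non-fire baseline.** Differencing "with fires" minus "without fires"
  assumes a non-fire background of 0 µg/m³ by default (`baseline_pm25`
  configurable); with a linear adult CRF the baseline cancels exactly, and
  for children it matters only near the breakpoint.

Deaths are computed per simulation year from that year's exposure and then
averaged, so El Niño-type met years show through; reports round deaths to
2 significant figures and reductions to integer percent, matching the
conventional precision of such tables and making comparisons well defined.

## Scenarios

Masks are defined and applied on the **fine** grid before aggregation, so a
partially-masked coarse cell loses exactly its masked fraction of mass —
this is what 1-km scenario definitions (peat maps, concession polygons)
require. `rank_sites()` defaults to ranking by averted deaths for a chosen
receptor with an exposure-benefit alternative; ties break by site name.
Site masks are exact cell sets; coarse-cell-level blocking is obtained by
passing a mask that covers whole coarse blocks.

# The synthetic domain

The generator produces every input with the statistical structure the
analysis assumes, on a toy domain that does not mimic any real geography:

| Parameter | Default | Meaning |
|---|---|---|
| `fine_grid`, `coarsening_factor` | 120 × 120, 10 | 1-km-like cells nesting into a 0.25°-like 12 × 12 coarse grid |
| `class_fractions` | 0.35/0.20/0.25/0.20 | initial intact/degraded/plantation/nonforest mix |
| `transition_rates` | degradation/clearing-dominated | per-5-year per-cell conversion probabilities |
| `fire_propensity` | 2·10³…1.2·10⁵ kg DM km⁻² month⁻¹ | per-class emission intensity; plantation/secondary and nonforest burn most |
| `peat_multiplier` | 8 | peat burns far more intensely per unit area |
| `seasonality` | Jul–Oct ≈ 80% of the year | burning-season weights |
| `elnino_cycle` | (1, 4, 1, 0.5, 2) | 5-year multiplier cycle with one strong event, echoing a 2005–2009-like window |
| `wind_bearing`, `anisotropy`, `plume_scale` | 225°, 0.6, 3 coarse cells | sensitivity kernels peak at the receptor and stretch upwind |
| `sens_amplitude` | 2·10⁶ (µg/m³)/(g/m²/s) | kernel peak; with the propensities above this puts burning-season exposures in the few-µg/m³ range typical of regional smoke |
| `frp_dropout`, `noise_sd` | 0.1, 0.3 | detection gaps (exercising the downscaling fallback) and lognormal mean-1 emission noise |

The kernel amplitude is receptor-independent: an adjoint cost function is a
population-*weighted mean*, so its magnitude does not grow with total
receptor population. Receptor differences in mortality come from population
counts in the health stage, and differences in exposure from geometry.
Each generator draws from its own stream at a fixed offset from the master
seed, so outputs are bit-reproducible and adding a generator never shifts
existing ones.

What the generator does **not** emulate: real coastlines or provinces,
satellite orbital sampling and detection efficiency, fuel-load maps,
secondary aerosol, or transport that violates nonnegativity/linearity.
Passing tests therefore demonstrate the correctness of the pipeline's
mathematics and accounting on inputs with the assumed structure — not the
realism of any particular regional forecast.

# Numerical choices and degenerate inputs

* Mass conservation in downscaling and fine/coarse projection agreement are
  exact identities, tested at 1e-12 relative tolerance; rate recovery on
  noise-free truth at 1e-10.
* Constant evidence layers make the VIF undefined and are an error, never a
  silent pass; perfect collinearity reports `Inf` and is flagged.
* `percent_reduction()` returns `NA` for a zero baseline (undefined), and
  `share_of_burden()` refuses a zero total.
* Priors are clamped away from 0/1 before the logit; empty evidence bins
  are handled by the +0.5 smoothing.
* Demand exceeding the eligible pool, grids that do not nest, missing met
  years, unmapped fire types and rates outside (0, 1) all fail fast with
  specific errors.

# Problem sizes

The test suite runs the property checks on the full 120 × 120 / 12 × 12
domain — a 5-year observation record plus a simulated decade of monthly
fields — and the unit tests on a 24 × 24 miniature; the acceptance script
projects 2020–2029 monthly on the full domain. These sizes keep the entire
suite under a minute on one core while leaving every property at the scale
the pipeline is meant for.

# Limitations

Beyond the generator's scope notes above: the adult CRF is a linear
approximation of an underlying nonlinear relationship, applied outside the
populations it was estimated in; emission factors for tropical peat are
uncertain and likely conservative; the framework carries no climate-driven
change in transport patterns (met years only repeat); and no economic or
morbidity endpoints are computed. Analyses of real regions should treat the
relative comparisons between scenarios, which cancel much of the shared
uncertainty, as the robust output — not the absolute death counts.
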