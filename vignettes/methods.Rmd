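---
title: "Models and methods behind wheatstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wheatstress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatstress)
```

`wheatstress` estimates the wheat yield losses caused by short-term
extreme drought and extreme heat around flowering, under baseline and
delta-change future climates.  This vignette is the package's own
account of the science: the models, their assumptions, the parameters
that matter, and the choices made where the design was genuinely open.

## The stochastic weather generator

Each site is described by monthly statistics (`site_climate_params()`):
Gaussian means and standard deviations of daily maximum and minimum
temperature, a first-order two-state wet/dry occurrence chain
(`p_wet_given_dry`, `p_wet_given_wet` per month), gamma wet-day amounts
(monthly shape and mean), and lognormal daily radiation around a monthly
mean with a global coefficient of variation.  `generate_series()` draws
365-day years (fixed month lengths, no leap days — the bias is
negligible for thermal-time bookkeeping and extreme-value indices), with
the occurrence chain and the AR(1) standard-normal temperature anomaly
running continuously across year boundaries and initialised at their
stationary distributions.  Daily `tmax` is the monthly mean plus the
scaled anomaly; `tmin` sits a fixed monthly diurnal range below `tmax`,
which guarantees `tmax >= tmin` by construction (the price is that the
generated `tmin` anomaly shares the `tmax` anomaly; `monthly_sd_tmin`
is carried for estimation output but does not drive generation).
Generated wet-day amounts are truncated below at 0.1 mm to avoid
degenerate gamma draws; a wet day in estimation is any day with
precipitation above 0 mm.

Future scenarios are built by the delta-change method
(`apply_delta()`): additive monthly offsets on temperature means,
multiplicative monthly factors on wet-day amount means and radiation
means.  Only first moments are perturbed.  GCM-derived changes in
variability and extremes are a real feature of full downscaling systems
that this generator deliberately omits: no formula for second-moment
changes is part of the delta contract here, and the omission means
scenario extremes change only through shifted means and phenology.

`estimate_params()` inverts the generator from observed daily series:
monthly sample moments, maximum-likelihood transition counts,
method-of-moments gamma fits, and the pooled lag-1 autocorrelation of
deseasonalised `tmax` (year breaks excluded).  A month with no wet days
gets zero transition probabilities and an undefined (NA) amount shape.

## The host crop model

The season simulator (`run_season()`) is a deliberately minimal
process-based host whose only job is to expose every quantity the
flowering-window stress mechanisms consume.  Its components:

* **Phenology** — cumulative thermal time `max(0, T_mean − base_temp)`;
  anthesis and maturity at cultivar-specific requirements (defaults
  1100 and +750 °C·d, base 0 °C, typical of spring wheat).  No
  vernalisation or photoperiod response, so warming translates into
  phenological acceleration at full strength; this matters for the
  directional experiments below.
* **Canopy** — LAI ramps linearly in thermal time to `max_lai` (6) at
  anthesis, then senesces linearly to maturity.  Light interception is
  Beer's law with extinction 0.6.  Because LAI is thermal-time driven,
  cultivar profiles that differ only in stress switches share identical
  canopies, which is what makes the paired protocol clean.
* **Growth** — biomass accumulates as `RUE × intercepted radiation ×
  supply ratio`, with `rue_ref` 1.1 g MJ⁻¹ (global radiation basis) and
  a linear CO₂ response `rue_co2_multiplier()`: +30 % per doubling of
  CO₂ against the 363.8 ppm baseline reference.
* **Water** — a single-store Priestley–Taylor balance
  (`water_balance_step()`; coefficient 1.26, net radiation 0.6 of
  global, latent heat 2.45 MJ mm⁻¹).  Demand splits into canopy
  transpiration (`f_int × ETp`) and soil evaporation.  Actual
  transpiration is limited by root-available water through a critical
  fraction rule (`f_crit` 0.5 of root-accessible capacity); the
  accessible fraction grows linearly with days after sowing
  (default 0.015 d⁻¹, full profile by ~day 67).  Water is conserved
  exactly: store in + rain = store out + ETa + drainage, and the tests
  assert it to accumulation precision.  ETp needs no wind or humidity,
  which the weather generator does not produce — that is why
  Priestley–Taylor rather than Penman–Monteith.
* **Canopy temperature** — an empirical surrogate for a full energy
  balance: `tcan = tmax_air + 5 °C × (1 − supply ratio) × min(1,
  rad/25 MJ)`.  A fully transpiring canopy sits at air temperature; a
  fully stressed one under high radiation runs 5 °C hot.  This is the
  largest fidelity gap in the package: it captures the sign and rough
  magnitude of water-status effects on canopy temperature but none of
  the aerodynamic detail.
* **Yield** — sink-limited through grain number × grain weight.  Ear
  mass at anthesis is 0.3 of anthesis biomass; grain number is
  `n_pot` (100 grains g⁻¹ ear) × ear mass × `R_D` × `R_H`; grain
  weight is `w_pot` (0.045 g) × `R_W`, capped by assimilate available
  for grain fill (post-anthesis growth plus 25 % retranslocation of
  anthesis biomass) per grain.  The cap means grain-number losses are
  partially — never fully — compensated by heavier grains, so extreme
  stress always costs yield.  How a leaf-layer canopy model converts
  ear mass to canopy-scale grain number is not observable from the
  outside; the `ear_mass_fraction` route is an explicit surrogate.

The package reports both combined evapotranspiration ratios (ETa/ETp)
and the pure transpiration ratio; the drought stress factor uses the
latter.

## Stress responses and windows

The drought stress factor `DSF` is the ratio of summed actual to summed
potential transpiration over the drought window; a window with zero
demand is defined as unstressed (`DSF = 1`).  The window spans 10 days
before to 5 days after anthesis.  Counted inclusively that is 16
calendar days; the quoted length of 15 days corresponds to dropping one
endpoint.  Both conventions are implemented
(`stress_windows("inclusive")`, the default, vs
`"exclusive_anthesis"`), selectable in the run config; the choice moves
`DSF` by at most one day's weight.  Whether `DSF` should average over
the window only or all of reproductive development is ambiguous; the
window-only reading is used because it is the one that makes the index
respond to *short-term* extremes.

Heat acts through the maximum canopy temperature over the meiosis
window (10 days before anthesis to anthesis, 11 days inclusive) for
grain number and over the early endosperm window (5–12 days after
anthesis, 8 days) for grain weight — single window maxima, not
day-by-day products, because the mechanism is triggered by the extreme,
not the mean.

The seven stress parameters ship as **non-calibrated placeholder
defaults** and are labelled as such: `dsgnt` 0.6, `dsgns` 0.2,
`dsgnr_max` 0.25 for drought; thresholds `t_n` 30 °C and `t_w` 35 °C —
the temperatures the cereal-physiology literature associates with
pollen-sterility damage before anthesis and early-endosperm damage
after it — with slopes `s_n` 0.08 and `s_w` 0.06 °C⁻¹, placing complete
grain-set failure near 42 °C canopy temperature.  Any quantitative use
on real sites requires calibrating all seven against field or
controlled-environment data.

## The paired protocol and the indices

`run_paired_protocol()` generates one weather series per site ×
scenario and runs three profiles on it: tolerant (both mechanisms off),
drought-sensitive-only, heat-sensitive-only.  Switching a mechanism off
suppresses its yield reduction but not the shared water-status and
canopy-temperature diagnostics, so indirect effects are retained; the
protocol asserts that anthesis dates agree across profiles.  Per-year
`DSI = 1 − Y_D/Y` and `HSI = 1 − Y_H/Y` are undefined at `Y = 0`; such
years (and failed seasons) are excluded and counted.  The 95th
percentile uses the fractional-rank linear-interpolation rule
(`(n−1)p+1`; for 100 sorted values, `x[95] + 0.05 (x[96] − x[95])`),
recorded in every output as `percentile_rule` because no single
percentile convention is canonical and third-decimal comparability
across tools depends on it.  The level-0.95 percentile is the
1-in-20-year loss (`return_period()`).

## Aggregation

Sites aggregate to countries by plain unweighted means; the per-country
*extreme site* is the argmax of the GCM-ensemble-mean index, selected
independently for drought and heat (they are often different places),
with ties broken lexicographically.  Rankings sort descending by the
extreme site's ensemble mean with a stable order, and report rank
changes against baseline.  Global summaries use plain site means and do
not substitute extreme sites; production weighting is deliberately
absent.

## What the synthetic fixtures emulate — and what they do not

The four archetypes span the contrasts the indices respond to:
`cool_variable` (cool season, wide temperature variability),
`hot_narrow` (hot season, narrow distribution), `wet_temperate` and
`dry_continental`.  Monthly means follow a sinusoid (warmest month July
in the north, January in the south); autumn sowing for the temperate
archetypes, spring for the continental ones.  A GCM-like delta ensemble
draws member warmings around a stated mean and spread with small
monthly jitter and uniform precipitation factors.

Two archetype behaviours are worth knowing when interpreting test
results.  First, the cool-variable archetype produces a higher
1-in-20-year heat loss than the hot-narrow one despite a cooler season,
because the wide across-year spread of flowering-window maxima crosses
the damage threshold more often than the hot site's narrow one — this
contrast is asserted in the tests.  Second, at fixtures whose flowering
windows run very hot (canopy maxima near 37 °C and beyond), the heat
index saturates at 1 (1-in-20-year total grain-set failure) and the
directional response to further warming inverts, because phenological
escape then dominates.  The warming experiments therefore use a
moderately water-limited continental fixture (annual mean tmax 13 °C,
amplitude 12 °C, wet-day probability 0.22, SAWC 150 mm, initial deficit
30 mm, sown day 70): drought stress is present at baseline and the heat
index has headroom.  On that fixture, uniform warming advances
anthesis, trims cumulative pre-anthesis ETp, lowers the extreme-drought
index and raises the extreme-heat index — the mechanism the pipeline
exists to demonstrate.

Passing these tests shows the mechanisms compose correctly at desk
scale.  It does not show skill on real sites: the fixtures have no
spatial correlation, no observed soils or cultivars, mean-only climate
deltas, and placeholder stress calibrations.

## Numerical choices and problem sizes

Reproducibility is seed-exact: every stochastic operation takes an
explicit seed, sub-seeds derive deterministically from (master seed,
site, scenario) via a small string hash below 2³¹, and identical inputs
give byte-identical outputs.  Index vectors snap accumulation round-off
at the interval ends (|ε| < 10⁻⁹) so yield-equality years report
exactly zero.  Percentile estimation refuses series shorter than 20
years.  Season failures (thermal time unmet, stress window truncated by
the season edge) are typed conditions, excluded and counted rather than
silently dropped.

The shipped experiments use 100-year series, 5-member delta ensembles
and up to five sites — sizes chosen so the full suite exercises every
mechanism, including the 1-in-20-year tail, in about a minute on one
CPU.  Longer series sharpen the tail estimates at linear cost.

## Known limitations

No nitrogen economy, pests, frost, vernalisation/photoperiod,
irrigation or sowing-date adaptation; no heat × drought interaction
term (the two indices are isolated by construction, not combined); no
second-moment climate change; the canopy-temperature surrogate and the
non-calibrated stress defaults are the two largest fidelity gaps, both
flagged above.
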