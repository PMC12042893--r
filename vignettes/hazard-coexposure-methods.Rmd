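---
title: "Methods: census-tract coexposure to heat, burn zones, and smoke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: census-tract coexposure to heat, burn zones, and smoke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazardCoex)
```

## The problem

Climate change drives three related heat hazards: extreme heat (EH),
wildfire burn zones (WFBZ), and wildfire smoke (WFS). They co-occur —
heat dries fuels, fires raise local temperatures and emit smoke that
travels far beyond the burn — and their joint footprint matters for
public health in a way no single-hazard summary captures. hazardCoex
operationalises the accounting: it classifies every census tract-day
as exposed or not to each hazard, builds coexposure flags for every
hazard combination under same-day and two-day rules, and summarises
exposure in tract-days and person-days, with trend tests on annual
series and descriptive disparity analyses across sociodemographic
groups.

The unit of account is the *tract-day*: one census tract on one
calendar day. When a hazard touches a tract, everyone in the tract is
assumed exposed, so person-days are tract-days weighted by tract
population. Both simplifications are deliberate and are the standard
trade-off for continental-scale, multi-year accounting.

## Hazard definitions

**Extreme heat** uses a dual threshold. A tract-day is EH when daily
maximum temperature meets or exceeds *both*:

* the tract's **relative threshold** — the 95th percentile of its daily
  maxima over all warm-season days (May 1 – September 30) in the
  baseline years (the first five study years by default). We use
  linear interpolation between order statistics (the type-7 rule, the
  default of `quantile()` and of NumPy); the percentile rule matters at
  the margin, so it is pinned down and tested against a sorted-array
  oracle.
* an **absolute threshold** of 32.22 °C (90 °F).

Both comparisons are inclusive (a day exactly at a threshold counts).
The relative threshold respects local acclimatisation; the absolute
gate prevents cool-climate tracts from labelling mild days as extreme.
Classification runs over all days of all years: the dual threshold
makes winter flags practically impossible, so no season restriction is
imposed beyond the one inside the threshold derivation.

**Burn zones**: a tract-day is WFBZ when at least one satellite-detected
active-fire point falls inside the tract that day (count ≥ 1). The
source data cannot distinguish prescribed burns from wildfires; both are
included.

**Smoke**: a tract-day is WFS when modeled wildfire-specific PM2.5
strictly exceeds a threshold — 0 µg/m³ by default, 5 µg/m³ as a
sensitivity setting. Strict exceedance means a modeled 0 is never a
smoke day, and tightening the threshold can only shrink the flag set (a
tested invariant).

## Coexposure

Same-day coexposure is the elementwise AND of hazard flags, per
combination (EH∧WFBZ, EH∧WFS, WFBZ∧WFS, and the triple). The two-day
sensitivity window flags day *d* for a pair (A, B) when A is active on
*d* and B within one day of *d*, or vice versa. Two readings of the
window rule are defensible — flag only the later day, or flag both
participating days. We flag **both** days (one EH day adjacent to one
WFBZ day yields two coexposure tract-days); the choice is isolated
behind the `window` option so the alternative is a localised change.
The triple under the two-day rule requires all three pairs to satisfy
the window rule on day *d*, which implies at least one hazard is active
on *d* itself. Same-day flags are always a subset of two-day flags,
and the implementation is tested for exact agreement with a brute-force
triple loop over (tract, day, combination).

## Exposure metrics

With \(E_i\) the exposure (or coexposure) days of tract \(i\) over the
window, \(P_i\) its population, \(N_{cts}\) the tract count,
\(N_{years}\) the year count:

* \(T_{year} = \sum_i E_i / N_{years}\) — region tract-days per year;
* \(T_{ct,year} = T_{year} / N_{cts}\) — days per tract per year;
* \(PDE_i = P_i E_i\) — person-days of tract \(i\);
* \(T_{person,year} = \sum_i PDE_i / N_{years}\);
* \(T_{person,ct,year} = T_{person,year} / N_{cts}\);
* \(T_{S,year}, T_{person,S,year}\) — the state analogues, summing
  exactly to the regional totals (a tested conservation law).

The per-year numerator is read as the region-wide (sum over tracts)
exposure in year *y*. A tract-day exposed to two hazards contributes
one day to each hazard's metric and one to their coexposure metric; no
deduplication is applied.

## Trend testing

Annual tract-day series are tested with the classical Mann-Kendall
test, implemented from its definition: \(S = \sum_{i<j}
\mathrm{sgn}(x_j - x_i)\), tie-corrected variance
\([n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18\), continuity-corrected
normal deviate, two-sided p. No seasonal or
autocorrelation-corrected variant is used. The implementation is
checked against an exhaustive-permutation exact test for \(n \le 7\)
and calibrated for type-I error on i.i.d. series of \(n = 15\) — the
study-design length, short enough that the package attaches a
small-sample caution flag to any series under 10 years. Series under
3 years are reported with missing statistics rather than an error, so
short demonstration runs still emit complete tables.

## Disparity analyses

All disparity outputs are descriptive (no inference). Quintile
composition bins tracts by the unweighted tract distribution of
exposure days (breaks at the 20/40/60/80th percentiles; ties fall to
the lower quintile; zero-population tracts excluded) and reports, per
racial/ethnic group, the percent of that group's population in each
quintile — 20% per quintile under an even distribution. Group
populations are \(P_i \times\) share, kept fractional. Because burn-zone
exposure is mostly zero, WFBZ and its coexposures use manual day-count
categories instead; the published cut-points are not stated, so the
defaults (0, 1–2, 3–5, 6–10, ≥ 11 days) are our own and configurable.
The vulnerability overlay flags tracts with SVI strictly above 0.9 and
at least one exposure day. Tribal-land comparisons report mean days per
tract in overlapping versus non-overlapping tracts, after restricting
to tracts with at least one burn-zone day. Top-N tables rank tracts by
cumulative days (ties to the lower tract id) and report percent aged
65+, percent with disabilities, percent non-white (100 minus the
non-Hispanic-white share), and percent below 150% of poverty, with the
all-tract average alongside.

## The synthetic generator

Real inputs (a ~4-km temperature grid, 1-km active-fire points, a 10-km
smoke surface, a tract inventory) cannot ship with a package, so a
generator produces inputs with the statistical structure the analysis
assumes:

* **Tracts** form a lattice of equal lon/lat squares. This is the one
  deliberately unrealistic choice: rectangle-on-rectangle intersection
  areas are exactly computable, so the zonal statistics have a
  hand-checkable oracle. Attributes mimic a Western-US inventory:
  populations around 4 000 (a configurable small fraction exactly zero,
  defaulting to the 62-in-18,106 rate of uninhabited tracts),
  Dirichlet race/ethnicity shares centred on the study-area mix,
  vulnerability as the percentile rank of a latent score (missing for
  zero-population tracts), a contiguous tribal block, and pseudo-states
  splitting the lattice by longitude.
* **Temperature** is a sinusoid peaking mid-July plus Gaussian noise
  plus planted heat events (Poisson per tract-summer, 1–5 days,
  a fixed excess), every planted day recorded in a truth ledger.
* **Fires and smoke**: Poisson ignitions per tract-year, 80% in
  June–September by default, burning 1–7 consecutive days with at
  least one fire point per burn day; smoke decays multiplicatively by
  Chebyshev lattice distance from the source (default halving per
  tract out to two tracts, 20 µg/m³ at the source) over a zero-inflated
  exponential background. Overlapping plumes combine by maximum. The
  Chebyshev plume is not advection; it is the simplest structure that
  reproduces the one phenomenon the analysis needs — smoke reaching
  tracts far beyond the burn zone.

Each simulator seeds deterministically from the single configuration
seed (tracts, then temperature, then fires/smoke), so components are
reproducible standalone and the bundle is bit-identical under a fixed
seed. The calendar is real (leap days included), dates ISO 8601.

What passing tests on this generator show — and what they do not: they
validate the *accounting machinery* (classification logic, window
algebra, metric formulas, conservation laws, rank-based trends) exactly,
but say nothing about meteorological realism, fire spread, or smoke
chemistry, and the published study-scale totals cannot be reproduced
without the real data.

## Numerical and design choices

* **Zonal aggregation** is the area-weighted mean (the source paper says
  only "aggregated"); weights are intersection areas under the
  cylindrical equal-area map, which is exact for lon/lat-aligned
  rectangles and is cross-checked against an independent geodesic area
  library. Cell-centroid and population-weighted variants were
  considered and rejected as either less standard or conflating
  population into a purely spatial step.
* **Point-in-polygon** uses closed lower/left, open upper/right edges,
  with the domain's outermost max edges closed and residual ties to the
  lowest tract id — every point lands in exactly one tract and
  conservation (counts + unassigned = points) is testable. Points
  outside all tracts are tallied, never silently dropped.
* **Temperature units**: fields declared in K or °F convert to °C on
  read (90 °F → 32.22 °C).
* **Thresholds at boundaries**: ≥ for both EH thresholds, strict >
  for smoke — taken literally from the definitions' wording
  ("equaled or exceeded" vs "exceeding").
* **Degenerate inputs**: empty baselines, misaligned matrices, negative
  counts or smoke, all-identical exposure distributions (quintiles
  undefined — the error points to manual categories), and empty
  comparison sides all raise early, named errors.
* **Planted-event recovery experiments** (in the tests and the
  acceptance script) plant sparsely (0.3 events per tract-summer) with
  zero noise. Sparsity is an identifiability requirement, not a
  convenience: with dense planting the events themselves make up more
  than 5% of the warm-season baseline in some tracts, the 95th
  percentile absorbs them, and perfect recall stops being a property of
  the classifier. With sparse planting, recall and precision of 1.0 are
  exact expectations.
* **Problem sizes** are chosen for fast, deterministic test runs: the
  default lattice is 6×6 over 15 years; oracle-equivalence checks use
  up to 20 tracts × 60 days; the permutation-exact trend check uses
  n ≤ 7 (5 040 permutations); type-I calibration uses 2 000 replicates;
  the end-to-end demo is 16 tracts × 2 years.

## Limitations

The generator's square lattice and isotropic plume are caricatures;
conclusions about real geography require real inputs through the same
interfaces (GeoJSON tracts, gridded daily fields, fire-point CSV).
Exposure is binary at the tract-day level — no intensity, no duration
weighting — and the two-day window credits both participating days, a
reading that roughly doubles pair counts relative to the
later-day-only alternative. Trend tests on 15 annual values have
limited power, and small p-values should be read as indicative. The
disparity analyses are descriptive; no uncertainty is attached.
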