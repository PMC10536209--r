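---
title: "Modelling olive phenology with chill, anti-chill and growing degree days"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling olive phenology with chill, anti-chill and growing degree days}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cacgdd)
```

## The model

Olive dormancy is sequential. Through winter the tree is in *endo-dormancy*:
it will not grow however warm it gets, and what it needs is cold. Once enough
chilling has accumulated, it passes into *eco-dormancy*, where growth resumes
as soon as enough warmth has accumulated. `cacgdd` models this with two
coupled accumulation processes on daily minimum/maximum temperature series.

### Chill and anti-chill days

Each day contributes *chill days* `Cd <= 0` and *anti-chill days* `Ca >= 0`,
computed in closed form from the single-triangle idealization of the diurnal
temperature course: temperature rises linearly from the minimum `Tn` to the
maximum `Tx` and falls back, and the chill (resp. anti-chill) units are the
areas of that triangle clipped between 0&nbsp;°C and the threshold
temperature `Tc` (resp. above `Tc`). Splitting by where `Tn`, `Tx` sit
relative to 0 and `Tc` gives six mutually exclusive cases (see
`?chill_anti_chill`), including the all-frozen case `Tx < 0` where both
contributions vanish.

Accumulation runs over a *dormancy season*, 1&nbsp;November to
31&nbsp;October. Starting from zero, only `Cd` is added until the running sum
first reaches the chilling requirement `Cr < 0` (endo-dormancy release); from
the next day only `Ca` is added until the sum first returns to zero, which is
the predicted **sprouting** day. Either requirement may go unmet by the end
of the season — in a hyper-cold climate chill may accumulate but anti-chill
never balance it, in a hyper-warm one chilling may never complete — and the
model then reports an explicit requirement-not-met failure rather than a
date.

### Growing degree days from the sprouting date

**Blooming** and **pit hardening** are forced with clamped growing degree
days,

\[ \mathrm{GDD} = \tfrac{1}{2}(T_x' + T_n') - T_b, \]

where the daily extremes are first clamped into `[Tb, Tx.base]` (plants gain
nothing below the base temperature or above the upper threshold). Forcing
starts dynamically at the sprouting date — each phase occurs on the first day
its cumulative GDD reaches the heating requirement `Hr`. Both phases
accumulate from sprouting, not bloom-to-pit: the reference requirements
(e.g. 437 GDD for blooming vs 1074 GDD for pit hardening for Carolea) share
a common origin, which also forces pit hardening to never precede blooming
since the two share `Tb` and `Tx.base` per cultivar. Using one chilling
requirement per cultivar and chaining subsequent phases through heat alone
avoids attributing a separate (physiologically meaningless) chilling
requirement to each phase.

## Numerical choices

* **Case-5 algebra.** The below-freezing-minimum, above-threshold-maximum
  case is implemented as `Cd = -(Tx^2 - (Tx - Tc)^2) / (2 (Tx - Tn))`: the
  chill area is the positive triangle area minus the part above `Tc`. This is
  the only reading that is continuous with the neighbouring cases and agrees
  with direct numeric integration of the triangle (`triangle_oracle()`), the
  package's independent cross-check.
* **Degenerate days.** When `Tn = Tx` every quadratic term takes its limit
  value 0, so a flat day never divides by zero and matches the zero-width
  triangle.
* **Daily mean.** The formulas use the symmetric mean `(Tn + Tx)/2`
  internally, which is what exact agreement with the triangle geometry
  requires; `use_supplied_tmean` restores a measured mean in the cases where
  it appears linearly.
* **Event-day conventions.** Phase dates are the first day whose end-of-day
  cumulative sum crosses the relevant threshold (daily resolution, no
  sub-day interpolation), and GDD forcing starts the day *after* the
  sprouting date — the event marks the end of that day's state. One-day
  conventions like this are within model error but must be fixed; this one
  is asserted throughout the tests.
* **Julian days.** `JDay` 1 is 1 January of the phenology year; days in the
  preceding November–December map to zero and negative values so the season
  index stays affine in JDay.

## Calibration

Parameters are fitted by minimizing the RMSE (days) between predicted and
observed dates: `(Tc, Cr)` against sprouting observations, then
`(Tb, Tx.base, Hr)` against blooming (and, re-using the blooming `Tb` and
`Tx.base`, the pit-hardening `Hr`), with each forcing record starting at its
observed sprouting day. Observations whose requirement is never met predict
the final season day (31&nbsp;October) — a finite penalty that degrades
smoothly as parameters approach feasibility, keeping the objective
informative for a stochastic optimizer.

The optimizer is a bounded real-valued genetic algorithm
(`ga_optimize()`): uniform initialization inside the search box, binary
tournament selection, blend crossover, per-gene Gaussian mutation
(sd = 10 % of the bound width) clipped back into the box, and elitism, so
the best value never worsens. Defaults are population 50, crossover 0.8,
mutation 0.1, elitism 2, up to 1000 generations with early stopping after
100 stagnant generations; a seed is mandatory and runs are bit-reproducible.
The default search boxes are `Tc` 7–14 °C, `Cr` −200…−80 chill units,
`Tb` 4–10 °C, `Tx.base` 25–35 °C, `Hr` 300–1400 GDD. The interface is
optimizer-agnostic: anything honouring the bounds and seed-determinism
contract could stand behind it.

Note that `(Tc, Cr)` can be partially confounded: distinct pairs may yield
near-identical date sets on sparse observations. The recovery contract in
the tests is therefore *date-level* — calibrated parameters must reproduce
the training dates — not parameter-level.

Validation follows the small-sample playbook: leave-one-out cross-validation
(`loocv()`, one calibration per held-out observation, absolute error in
days), plus Taylor-diagram statistics (`taylor_stats()`: Pearson r, the
sd ratio, and the centered RMSE normalized by the observed sd, which satisfy
the Taylor identity exactly).

## The synthetic data generator

No site observations ship with the package, so `simulate_weather()` and
`simulate_observations()` make the whole workflow testable end to end. A
site is a sinusoidal annual cycle plus AR(1) anomalies:

\[ m(d) = \bar{T} - A \cos\!\big(2\pi (d - d_{\min}) / 365.25\big), \]

with the anomaly added identically to `tmin` and `tmax` so the diurnal range
(and `tmin <= tmax`) is preserved exactly. Defaults emulate a Mediterranean
olive site: annual mean 17 °C and half-amplitude 10 °C (February around
7 °C, August around 27 °C, matching the envelope of Italian olive-growing
sites whose annual means span roughly 14–19 °C), minimum at day 36,
diurnal range 8 °C, anomaly sd 2 °C with lag-1 correlation 0.7.
`simulate_site_network()` shifts the annual mean by per-site offsets to
emulate that multi-site thermal spread. Observations are forward-model
chains plus rounded Gaussian day noise (phenological observations are
calendar dates); site-years failing a requirement are dropped and counted,
mirroring how real non-fulfilment yields no date.

What the generator does *not* emulate: skewed or regime-dependent anomaly
distributions, heatwave/cold-spell clustering beyond AR(1), spatially
correlated noise between sites, elevation effects, or observation biases
that correlate with weather. Passing the recovery tests therefore shows the
estimation machinery is self-consistent under realistic thermal structure —
not that field data of this quality will calibrate equally well.

## Spatial projection

`project_grid()` applies a calibrated cultivar cell-by-cell over a regular
0.1° latitude–longitude grid. The default **mean-year** mode wraps each
cell's 365-entry day-of-year climatology (built by `build_climatology()`
over e.g. 30 years, 29 February dropped) into a single November–October
season and runs the chain once per cell, matching a "long-term mean year"
projection; a **per-year** mode runs every year of a dated series grid and
averages the successful Julian days, as a sensitivity alternative — the two
differ where the response to interannual variability is nonlinear. Cells
failing a phase are masked for that phase and all later ones (hyper-cold
cells, e.g. high mountains, fail this way). `difference_map()` subtracts an
early-cultivar raster from a late one, propagating masks; it is
anti-symmetric by construction.

Grid and raster files are plain long-format CSV (`lat,lon,doy|date,tmin,tmax`
and `lat,lon,jday` with a declared fill value for masked cells): simple,
diffable, and round-trip lossless at full precision.

## Problem sizes and runtime

The test-suite workloads are sized for a single CPU: oracle equivalence
sweeps 10^4 random days at 10^4 integration steps; noise-free recovery uses
6 seasons (3 synthetic sites at −2/0/+2 °C offsets × 2 years); the noisy
cross-validation envelope uses 20 replicates of 12 observations
(4 sites × 3 years, observation noise sd 4 days) with a reduced GA budget
(population 30, ≤ 40 generations); the spatial check projects the full
150 × 150-cell synthetic gradient (a 15° × 15° window at 0.1°), which takes
on the order of ten seconds per cultivar. Full-budget calibrations
(population 50, 1000 generations) remain the recommendation for real use.

## Known limitations

* Temperature-only: photoperiod, rainfall, latitude and management effects
  on phenology are out of scope.
* Daily resolution: no sub-daily chill metrics (chill portions, Utah units)
  and no sub-day interpolation of event dates.
* The failure penalty (31 October) is a pragmatic optimizer device, not a
  biological statement.
* Mean-year projection suppresses interannual nonlinearity; use per-year
  mode to probe it.
* Nearest-cell extraction (`extract_cell()`) does no interpolation or
  elevation correction.
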