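---
title: "Modeling residential NO2 exposure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling residential NO2 exposure: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(no2home)
```

This vignette is the package's own account of its model: the assumptions, the
parameters that matter, the numerical choices, and the places where the design
was genuinely open and a choice had to be made.

## The physical model

A dwelling is a network of well-mixed zones. For each species, zone
concentrations obey the linear balance

$$\frac{dC_z}{dt} = \frac{1}{V_z}\Big[\sum_y Q_{yz} C_y - \sum_y Q_{zy} C_z
  + Q_{out,z}\,C_{out}\Big] + \frac{S_z}{V_z} + d\,C_z$$

with three species per run: the stove pollutant (`NO2_stove`: indoor source,
zero outdoors, first-order decay $d$), an infiltration tracer (`CONTA`: no
indoor source, 100 ppbv outdoors, decays like NO2) and an inert air-exchange
tracer (`CONTB`: 100 ppbv outdoors, no decay, zero initial indoor value).
Because `CONTA` is held at 100 ppbv outdoors, its indoor concentration is a
percent infiltration, and outdoor-attributable NO2 for any location is
`conta_exposure * outdoor_no2 / 100` — one simulation serves every outdoor
concentration. `CONTA` is initialized at its steady state so its 24-h mean is
a valid infiltration percentage without burn-in; `CONTB` must start at zero by
definition of the time-constant method.

**Well-mixed assumption.** A zone's concentration is a single number; there is
no within-room gradient, no vertical stratification, and no chemistry beyond
first-order loss. This is the standard multizone idealization; it is why range
hoods are modeled as *source scaling* (emission times $1-CE$ while the hood
runs) rather than as exhaust fans — a modeled exhaust fan would remove
well-mixed air, but real hoods capture emissions before they mix. A
recirculating hood is a hood with $CE = 0$ (filter NO2 removal degrades within
weeks, so no credit is taken). Pilot lights are not modeled.

**Airflows.** A full pressure-network airflow solution is deliberately not
reimplemented. The downstream exposure mathematics needs realistic flow
*magnitudes* with the right qualitative drivers, not exact duct physics, so
leakage flows scale as

$$Q = Q_{ref}\,(a\,w + b\sqrt{|\Delta T|} + c)$$

with windspeed $w$ (m/s), indoor–outdoor temperature difference $\Delta T$
(K), defaults $a = 0.08$, $b = 0.04$, $c = 0$. Interzone openings carry fixed
bi-directional flow; open windows add their reference flow; every path is
bi-directional with equal flow each way, so each zone's air inflow equals its
outflow *by construction* and no balancing step can fail. A forced-air system
adds recirculation (default 5 zone-volumes/h) between each zone and a hub
zone whenever the ambient temperature is outside 15–25 °C (heating or cooling
season). Opening "the windows" opens the kitchen, every bedroom, and the
living-room window together.

The synthetic floorplans are calibrated only to the published air-exchange
anchors: leakage reference flows are sized to give 1.5 air changes per hour
(ACH) at the reference driver (10 m/s wind, 25 K difference, where the driver
equals 1) and window flows 4.5 ACH, so a windy cold day with windows open
gives 6.0 ACH, and still air at equal temperatures with closed windows gives
0 — the two anchors of the plausible residential range (typical conditions,
~4.5 m/s and a 10 K difference, land near 0.7 ACH from leakage alone).

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| decay rate $d$ | −0.86 | h⁻¹ | central literature surface-loss rate; uncertainty spans −2.07 to −0.17 |
| burner emission | 48 (= 25 mL/h) | mg NO2/h | average burner just above medium heat |
| stove-use levels | 0.64 / 31 / 199 | mg NO2/day | 5th/50th/95th percentiles of gas burned |
| day types | 2 / 4 / 1 days per week | — | no-cook / typical / heavy; heavy day emits 3× typical so the weekly mean matches the level |
| hood non-use | 0.64 houses, 0.72 apartments | probability | monitored-hood survey values |
| capture efficiency | 0–0.95 spectrum | fraction | 15-hood spectrum; recirculating = 0 |
| kitchen occupancy | 5 / 35 / 150 | min/day | 5th/50th/95th percentile anchors |
| conversions | 20 °C, 101325 Pa | — | reproduces both printed pairs 10 µg/m³ ↔ 5.2 ppbv and 25 mL/h ↔ 48 mg/h (25 °C would give 47 mg/h); molar mass fixed at 46.0055 g/mol |
| benchmarks | 5.2 long-term, 100 acute | ppbv | WHO guideline; WHO 1-h (~100 ppbv) and EPA 100 ppbv coincide as implemented |

Every behavioural payload is a configurable level of a `scenario_axis`; the
defaults above are central published values, and the full level grids of the
original behavioural surveys are not reproduced — which is why they are
configuration, not constants.

## Numerical choices

* **Integration.** Within a 10-min interval, flows and sources are constant,
  so the linear system is advanced *exactly* with a Van Loan augmented-block
  matrix exponential that yields the step transition, the forced response and
  the running integral in one call. The 10-min outputs are therefore exact
  interval means, not instantaneous samples, and the method is valid for
  singular flow matrices (closed systems) where a resolvent-based formula
  would fail. The `internal_timestep` setting is retained for interface
  completeness but does not affect accuracy. The test suite cross-checks
  1–3-zone configurations against an independent `deSolve::lsoda` solution
  (RMS agreement well under 0.5%).
* **Air-exchange recovery.** The time constant is located by log-linear
  interpolation of $1 - C/C_{out}$ at interval midpoints — exact in time for
  a single-exponential rise — then corrected for interval averaging: a 10-min
  mean lags the instantaneous curve by $\log(\sinh(kh/2)/(kh/2))/k$, which
  matters at high $k$ (a ~4% bias at 6 ACH if ignored). With the correction,
  known single-zone rates from 0.1 to 6 ACH are recovered to well within 2%.
  If the 63.2% threshold is never reached in 24 h the estimate is returned
  censored with a lower-bound flag instead of a number.
* **Acute windows.** The hour-averaged exposure is the mean of intervals
  $i..i+5$, maximized over the 139 *complete* windows in the day. Wraparound
  windows are rejected because the modeled day is a standalone 24-h period,
  not a periodic signal.
* **Degenerate inputs.** Zero-leakage (sealed) dwellings, zero decay, zero
  emission and point-mass Monte Carlo inputs are all legal and tested; the
  CONTA steady-state initialization falls back to zero when there is no
  outdoor exchange.
* **Skew-normal fit.** The decay sampler's three anchors (median, equal-tailed
  2.5th and 97.5th percentiles) determine location, scale and shape uniquely:
  shape is solved by root-finding on the standardized quantile-spread ratio,
  then scale and location follow linearly. The CDF is evaluated by direct
  quadrature of the density, so no distribution package is required.

## The scenario grid

Six axes with level counts 4 (hood) × 3 (stove) × 5 (occupancy) ×
3 (windspeed) × 3 (windows) × 4 (temperature). The first four are
geography-independent (180 combinations); window weights depend on the
temperature band, giving 540 weighted scenarios per band; the full product is
2,160 per floorplan. Scenario weights are products of level weights,
renormalized; every grid's weights sum to 1 to within 1e−9.

Two source-document ambiguities are resolved as configuration: the prose
level count for hood use ("five values") conflicts with the printed product
4 × 3 × 5 × 3 = 180, so the printed products are the defaults and all counts
are configurable; and the temperature conditioning is described both as two
distributions (<15 °C / ≥15 °C) and as nine — the two-band version is
implemented, each ZIP mixing one cold and one warm distribution 50/50 (the
mix weight is a per-ZIP column). Within a band, simulations run at the
band's weight-averaged ambient temperature; the temperature axis's four
levels are retained for the full-grid cardinalities and the band averages.

Because the stove channel is linear in emission, each floorplan × band needs
only 9 physical simulations per cooking pattern (windspeed × window
schedule), and the 540-scenario table is assembled by scaling with the
stove-use level, day-type multiplier and hood factor $1-CE$ — the scaling
commutes with both the chronic mean and the acute max because both are
positively homogeneous.

## Aggregation conventions

* The printed aggregation formulas carry a trailing division by 180 × 24
  alongside weights that are stated to be normalized; applied literally the
  divisor would not return a mean, so the normalized-weight double sum is
  implemented and the divisor dropped.
* The whole-population adjustment is implemented as *multiplication* by the
  gas-stove fraction (electric households contribute zero), despite the
  source wording "divided by the fraction": division is dimensionally
  inconsistent with stoves contributing ~10% of total exposure at a ~40% gas
  share, which multiplication reproduces. The division reading remains
  available behind `divide = TRUE`.
* Exceedance indicators use `conc >= threshold` and are evaluated on total
  (stove + outdoor) per-scenario exposure before weighting.
* The outdoor multiplier `MC_outdoor = DR × (1 − CE)` is implemented exactly
  as specified even though a hood affecting outdoor-attributable exposure is
  physically surprising; it inherits the hood factor because the source
  defines it that way.
* CI propagation applies the summary function separately to lower bounds,
  central estimates and upper bounds; this is valid for monotone summaries
  (mean, max, population-weighted mean) and a warning is emitted if the
  result is unordered.

## What the synthetic data emulate — and what they do not

The generators reproduce the *statistical structure* the analysis relies on:
right-skewed outdoor NO2 (lognormal solved from median 4.9 / mean 7.7 ppbv),
a ~40% gas-stove share, a positive density–NO2 relationship (r² ≈ 0.2 for the
linear regression on log density, via a shared Gaussian factor), denser ZIPs
skewing multifamily and small-floor-area (logistic-style log-linear tilt),
behavioural percentile anchors, and a floorplan library spanning every
housing-stock cell with a few shared cells to exercise the equal-split
weighting rule. Counties are contiguous blocks of ~10 ZIPs.

They do **not** emulate real geography: no spatial autocorrelation, no real
ZIP's values, no joint distribution of housing and climate beyond the stated
directions, and no educational-attainment adjustment of cooking time. Passing
tests therefore demonstrate that the *pipeline machinery* is correct under
realistic marginal structure — not that any specific national exposure number
is reproduced. National-scale headline estimates depend on the real housing
stock, outdoor surfaces and floorplan library, which are outside this
package's scope.

## Problem sizes

The default demonstration pipeline uses 8 floorplans × 2 bands ×
540 scenarios and 200 ZIP codes (~10 s on one core); the full synthetic
configuration (24 floorplans, 1,000 ZIPs, 10,000 Monte Carlo iterations)
completes in under a minute. The test suite runs 1–3-zone oracle comparisons
and a miniature end-to-end pipeline (4 floorplans, 12 ZIPs) twice for
determinism.

## Interface notes

The pipeline stages (`synth`, `simulate`, `uncertainty`, `aggregate`,
`report`) are exposed as plain R functions orchestrated by `run_pipeline()`;
intermediates are plain CSV/JSON so each stage is independently inspectable
and re-runnable from cache, and a manifest records the seed, configuration
and an MD5 checksum of every output.

## Known limitations

Only stove and outdoor channels are modeled — no ventless heaters,
cigarettes, flue spillage, in-vehicle or workplace exposure. No humidity or
non-ideal-gas corrections. Hood behaviour is on/off with a fixed capture
efficiency while cooking. The uncertainty model assumes exposure responds
linearly to its multiplicative factors (a full Monte Carlo through the
simulator would relax this). The Monte Carlo cooking-minutes factor is the
full behavioural spread, so the resulting intervals are wide by construction
under the synthetic conditions.
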