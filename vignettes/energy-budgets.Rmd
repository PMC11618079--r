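---
title: "Methods: bio-logger energy budgets of partial migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bio-logger energy budgets of partial migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migenergy)
```

## The question and the pipeline

In a partially migratory songbird population, some individuals fly south for
the winter while others stay. Wintering in a warmer place should reduce the
energy spent on thermoregulation; migrating costs flight energy. This package
implements the full analysis chain needed to put numbers on that trade-off
from implanted bio-logger data: 30-min heart-rate (`f_H`, bpm, a proxy for
metabolic rate) and core body-temperature (`T_b`, °C) series per bird, plus
hourly ambient temperature (`T_a`) series for the breeding and wintering
areas.

The stages are: (1) synthetic data generation, (2) quality-index (QI) error
calibration and filtering, (3) gradient-boosted classification of nocturnal
migratory flight and derivation of departure/arrival/stopover events, (4)
calendar-season and event-centred strategy comparisons, (5) a one-node
biophysical heat-balance model of thermoregulatory power, and (6) the
flight-cost versus thermoregulatory-savings accounting. Every stage is a
package function; the scripts under `analysis/` are thin drivers.

## What the generator emulates

`sim_config()` + `simulate_dataset()` produce a population with the
statistical structure the downstream stages must recover:

* day/night baseline means for `f_H` and `T_b` with per-bird intercepts and
  AR(1) residuals. Published field anchors constrain *effects*, not
  baselines, so the nocturnal `f_H` mean (374 bpm) is back-derived from the
  flight elevation (+199 bpm being a 53.2% rise over baseline); all means are
  configuration inputs, not claims.
* a nocturnal pre-departure ramp for future migrants: a multiplicative
  `f_H` reduction growing linearly from 0 at 28 days before fall departure to
  −19.5% at departure.
* flight nights: +199 bpm and +1.23 °C during the flight bout (bout length
  drawn per night, default 4–8 h from dusk), and a post-arrival `f_H`
  recovery dip decaying over 8 days.
* a resident midwinter `T_b` decline of 0.18 °C (over 15 Nov–28 Feb by
  default), producing the warmer-wintering-site `T_b` contrast in migrants
  while the winter `f_H` contrast stays zero. The decline is scoped to the
  calendar midwinter rather than the migrant-absence window so that
  migration-night contrasts remain exactly the configured flight effects.
* ambient series: a seasonal + diel sinusoid with hourly AR(1) weather noise;
  the wintering series is offset by +5.7 °C with weather noise correlated at
  0.7 with the breeding site (south-west European winter weather shares
  synoptic systems; the correlation also keeps the realized winter offset
  within ~0.1 °C of the configured value). Quantile series (q25/q75) are
  pointwise offsets of the wintering mean.
* migration phenology: departures uniform within a fall window, flight
  nights per journey drawn as `min + Binomial(max − min, p)` with `p` set so
  the mean is 4 (bounded 1–9), Poisson-distributed stopover runs between
  flights, winter arrival the day after the last fall flight, and a
  symmetric spring journey.
* measurement corruption: four QI classes with corruption probabilities
  (0.02, 0.08, 0.20, 0.50) spanning the 15% keep/discard boundary; a
  corrupted value is the true bpm halved or doubled (missed or
  double-counted ECG beats). Every 120th record per logger (60 h at 30-min
  cadence) carries the true value, mimicking the periodically saved raw ECG.
  `T_b` is never corrupted (factory-calibrated sensor).

What the generator does *not* emulate: weather-driven short-term metabolic
responses, within-night activity structure beyond the flight bout, torpor,
individual differences in insulation, logger failure/battery death, and any
correlation between corruption and physiological state. Passing tests
therefore demonstrate that the pipeline recovers effects of the configured
form and size under realistic noise — not that it would be unbiased against
every pathology of real field data.

Night is defined from the sunrise equation (solar-declination sinusoid) at
the configured latitude (default 47.7° N), with solar noon fixed at 12:00
UTC. This avoids an ephemeris dependency; civil twilight is approximated by
the geometric day/night split. Nights are indexed by the date at dusk.

## Quality control

The logger's QI is computed from each logger's own signal history and is not
comparable across loggers, so error rates are calibrated per (logger, QI)
cell from the truth subsamples: a measurement is *wrong* when its relative
deviation from the ECG-derived rate exceeds `mismatch_tolerance` (default
0.10 — the error-rate definition is a documented choice; the magnitude
threshold makes halving/doubling failures unambiguous). Cells with fewer
than 5 truth samples get an undefined rate — never zero — and records in
uncalibrated cells are excluded. The filter keeps records whose cell rate is
strictly below 15% and whose `f_H` lies in 60–800 bpm (the plausible range
is field-derived in the original study and config-exposed here). `T_b`
records pass through independently.

## Flight classification and events

Features per measurement: raw `f_H` and `T_b`, logger identity as an integer
category, per-bird z-scores, differences from the per-bird mean, and the
proportional `T_b` change versus the previous interval ("proportional
increase" is ambiguous; previous-interval is the adopted definition).
Scaling statistics use each bird's earliest records (before the fall
departures) so flight intervals cannot leak into the baseline.

The classifier is boosted trees (xgboost, logistic loss; 500 trees, depth 3,
learning rate 0.05 — the method family is fixed, the hyperparameters are
defaults of this implementation), trained single-threaded for determinism.
Nights are called *flight* when ≥ 25% of their nocturnal measurements are
labelled flight (`night_fraction`, exposed): migrating birds rarely fly the
whole night, so a quarter of the night suffices. Events follow from night
calls: fall departure = first flight night, winter arrival = day after the
last fall flight night, stopovers = stationary nights in between; spring
symmetric. On noise-free data this recovers the generator truth exactly
(a unit test asserts it).

## Pairing, seasons, stages and the comparison models

Calendar seasons are 1–7 September (fall), 3 December–17 January (winter;
46 days inclusive) and 2–10 April (spring; a span of 8 days from start to
end, the convention under which the window is reported). Eight
event-centred stages align birds on their own events: 35 d pre-departure,
fall migration/stopover, 14 d winter arrival, 21 d spring pre-departure,
spring migration/stopover, 14 d spring arrival; departure day is offset 0.

Resident-to-migrant pairing matches each resident measurement to at most one
same-sex migrant measurement at the same timestamp, distributing residents
round-robin (seeded random order) over the same-sex migrants present, so no
resident measurement is referenced twice — the pseudoreplication guard. The
even distribution is implemented as per-timestamp round-robin because only
the evenness requirement, not an algorithm, is fixed; per-timestamp load
differs by at most one.

Serial correlation is thinned by discarding a random 30% of each bird's
records. Season contrasts use `lmerTest::lmer` with strategy × season ×
day-phase plus sex, random intercepts for bird and date, and
Bonferroni-adjusted migrant-minus-resident contrasts per cell (asymptotic
degrees of freedom — Satterthwaite on 10^5 rows is needlessly slow and
changes nothing at these sample sizes). Event-centred comparisons use
`mgcv::gam` with a penalized spline over day offset per strategy, sex, and
random intercepts for bird and date; *significant windows* are maximal
offset runs where the two 95% confidence bands do not overlap, matching how
the accompanying figures are read. CI non-overlap is conservative relative
to a formal interaction test; that is acceptable here because the windows
are descriptive.

## The heat-balance model

The thermoregulation stage answers: given the bird held the `T_b` its logger
recorded while sitting in air at `T_a`, how much metabolic power did that
require? The bird is a one-node prolate ellipsoid (axis ratio 2) of flesh
wrapped in plumage:

* geometry from mass: volume `M/ρ` (ρ = 1000 kg m⁻³), surface areas from
  the standard ellipsoid approximation (exponent 1.6075), outer surface at
  semi-axes enlarged by the plumage depth; the characteristic dimension for
  convection is the equal-volume sphere diameter.
* series resistance: flesh shell (5 mm, 0.5 W m⁻¹ K⁻¹), plumage (10 mm,
  0.04 W m⁻¹ K⁻¹ — an effective feather–air composite a little above still
  air), and a combined convective–radiative boundary layer,
  `Nu = max(2, 0.37 Re^0.6)` and `h_rad = 4εσT_film³` with ε = 0.95 and the
  film temperature fixed at the midpoint of `T_b` and `T_a`. Fixing the film
  temperature makes the balance closed-form; a bisection solve of the same
  balance (solving for the outer-surface temperature) agrees to < 10⁻⁶ W
  over a 100-point parameter grid, which bounds the linearization at
  numerical noise rather than a physical approximation error.
* required heat loss `Q_req = (T_b − T_a)/R_total`, floored at zero when the
  air is warmer than the body (no heating load is modelled). Total metabolic
  power is `max(basal, Q_req)` — below the thermoneutral load the bird idles
  at basal power (Lasiewski–Dawson passerine BMR, ≈1.09 W at 90 g, a
  configuration input). Both total and above-basal columns are always
  emitted; strategy differences use the total.

With the blackbird defaults the whole-animal thermal conductance is
≈0.05 W K⁻¹, in the range of classic passerine measurements, and
`Q_req(39.5 °C, 0 °C) ≈ 2.0 W ≈ 1.8 × BMR` — a plausible winter working
level. Evaporative and respiratory heat loss, radiation load, posture and
microclimate selection are deliberately omitted (cold-season regime); this
is a transparency-for-fidelity trade against full mechanistic endotherm
models, and it is why absolute energy totals are reported as
model-conditional quantities rather than field estimates.

Each bird's experienced `T_a` follows its events: residents stay on the
breeding series (scenario offsets +0/+1/+2 °C are added only while migrants
are off-site, bracketing micro-climatic buffering); migrants converge
linearly from breeding to wintering temperature, one step per flight night
(weight `k/n` after the k-th of n fall flight nights, updating at night end
at day resolution), reversing symmetrically in spring. The 3 × 3 scenario
grid crosses resident offsets with the wintering mean/q25/q75 series.

## The budget

Flight power is the allometric `y = 52.6 M^0.74` W (M in kg; ≈8.85 W at
90 g); flight energy multiplies it by total flight time. Because quality
filtering removes a share of measurements, flight duration is estimated per
called flight night as the flight fraction among kept intervals times the
full nocturnal grid size of that night (taken from the `T_b` record set,
which is complete) — counting labelled intervals directly would understate
duration by exactly the discard rate. Savings are the difference in mean
per-bird cumulative total thermoregulatory energy between strategies over
the migrant-absence window; the flight fraction is 100 × mean flight energy
/ savings, with its range over the scenario grid. The seasonal trend model
is a hierarchical GAM of daily per-bird energy on day-of-series by strategy
with a bird random intercept, reported with 95% bands and their
non-overlap windows.

`budget_recovery_config()`/`budget_recovery_params()` define the end-to-end
recovery condition: a configuration whose ground-truth flight/savings ratio
sits near 7%. Reaching that regime at blackbird scale requires the
high-conductance end of the biophysical envelope (wind 8 m s⁻¹, 2.5 mm
effective plumage — an exposed winter microsite, the regime mechanistic
endotherm models occupy once wind is included, and the regime in which
field-scale savings estimates of order 10⁴ kJ arise), concentrated
ten-day departure windows, and 2.5–4.5 h flight bouts. These values were
fixed once at design time; the recovery tests compare pipeline estimates
against the generator truth of the same run, not against the design point.

## Numerical and degenerate-input choices

* All randomness flows through explicit integer seeds; xgboost runs
  single-threaded; identical config + seed is byte-identical output.
* AR(1) noise is stationary (marginal sd as configured, innovation sd
  scaled by `sqrt(1 − φ²)`).
* Thinning removes `round(fraction · n)` records per bird, exactly.
* Undefined QI error rates are `NA`, never 0; filtering is idempotent and
  never mutates records.
* A bird with a single measurement yields no feature rows (warning); the
  first interval per bird has no `T_b` change and is dropped.
* Ambient gaps are forward-filled up to 4 intervals, then the run aborts
  naming the first offending timestamp.
* Spline basis sizes shrink automatically when a stage window has fewer
  distinct day offsets than the default basis.
* Event-centred fits refuse below 3 birds per strategy; the trend model
  likewise.

## Problem sizes

The default study population is 20 birds (12 residents, 8 migrants) over one
logger year at 30-min cadence, ≈213,000 records — large enough that the
winter contrasts and the classifier's held-out evaluation are stable, small
enough that the whole pipeline runs in well under a minute. The
event-centred analyses use 15 + 15 birds; the null-coverage calibration uses
50 replicates of a 6 + 6 population restricted to the winter window. These
sizes are the package's chosen study conditions for its synthetic
experiments.

## Known limitations

* The heat-balance model is one-node and dry; it cannot reproduce the
  absolute output of a full microclimate endotherm model, and absolute kJ
  totals should be read as model-conditional.
* The classifier's near-perfect synthetic performance reflects the large
  configured flight elevation against AR(1) noise; real ECG-derived series
  carry artefact structure the QI model only caricatures.
* Pairing discards resident measurements beyond one per migrant per
  timestamp; with many more residents than migrants much resident data goes
  unused, as in the matched design it implements.
* Calendar season windows are population-specific constants, configurable
  but not estimated from the data.
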