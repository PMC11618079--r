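# migenergy

Energy budgets of partial migration from heart-rate and body-temperature
biologging.

In partially migratory songbird populations, some individuals winter in
warmer areas hundreds of kilometres away while the rest stay on the breeding
grounds. `migenergy` is an analysis workflow for implanted bio-logger data
(30-min heart rate *f*<sub>H</sub> and core body temperature *T*<sub>b</sub>)
that quantifies the energetic consequences of that decision: it classifies
migratory flight nights from the physiological series, compares strategies
around the birds' own departure and arrival events, estimates the
thermoregulatory cost of wintering cold via a biophysical heat-balance
model, and closes the ledger against the allometric cost of the migratory
flights. A synthetic-data generator produces whole populations with known
ground truth, so every stage is testable without field data.

## The models at the core

**Flight-state classification.** Boosted decision trees on per-measurement
features (*f*<sub>H</sub>, *T*<sub>b</sub>, logger identity, per-bird
z-scores, deviations from the bird's mean, proportional *T*<sub>b</sub>
change), aggregated to night-level calls and then to
departure/arrival/stopover events.

**Event-centred comparison.** Resident measurements are paired one-to-one to
simultaneous same-sex migrant measurements (no value reused —
pseudoreplication-free), serial correlation is thinned by discarding 30% per
bird, and strategies are compared with linear mixed models (random
intercepts for bird and date, Bonferroni post hoc) and penalized-spline
smooths over the day offset from each migrant's own events
(significance = 95% CI non-overlap).

**Thermoregulation.** A one-node endotherm heat balance: the bird is a
prolate ellipsoid of flesh wrapped in plumage, and the power needed to hold
the observed *T*<sub>b</sub> against the experienced *T*<sub>a</sub> is

&nbsp;&nbsp;*Q*<sub>req</sub> = (*T*<sub>b</sub> − *T*<sub>a</sub>) / *R*,&nbsp;&nbsp;
*R* = *R*<sub>flesh</sub> + *R*<sub>plumage</sub> + 1/((*h*<sub>conv</sub> + *h*<sub>rad</sub>) *A*<sub>outer</sub>),

with Nu = max(2, 0.37 Re<sup>0.6</sup>), *h*<sub>rad</sub> = 4εσ*T*<sub>film</sub>³,
and total metabolic power floored at basal. Migrants' experienced
*T*<sub>a</sub> converges linearly from breeding to wintering temperature
over their migration nights; a 3 × 3 scenario grid crosses resident
micro-climate offsets (+0/+1/+2 °C) with wintering-site temperature
quantiles (mean/25%/75%).

**Flight energetics.** Allometric flight power *y* = 52.6 *M*<sup>0.74</sup> W
(*M* in kg) times classified flight duration, reported as a percentage of
the thermoregulatory savings.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
populations. A condensed version:

```r
library(migenergy)

res <- run_pipeline(budget_recovery_config(seed = 1),
                    params_fn = budget_recovery_params)

res$evaluation
#> measurement-level AUC 1.000, night-level agreement 100.0%

res$savings_grid[res$savings_grid$scenario == "off0_mean", ]
#>    scenario delta_kJ  fold
#>   off0_mean    12990 1.138

res$flight_fraction[c("central_pct", "min_pct", "max_pct")]
#> 5.7% of the thermoregulatory savings (4.2-29.2% over the scenario grid)
```

Reading: under the baseline scenario, residents spent about 12,990 kJ more
on thermoregulation than migrants over the separation period (a 1.14-fold
difference), while the classified migratory flights cost on average 741 kJ
per migrant — 5.7% of the savings. The generator's ground truth for this
configuration is a savings of 14,625 kJ (fold 1.158) and a flight/savings
ratio of 6.75%, so the pipeline recovers the configured budget within its
tested tolerances. `analysis/04_stage_compare.R` additionally shows the
event-centred smooth flagging the nocturnal pre-departure *f*<sub>H</sub>
depression from day −20 through departure (injected onset: −28 d, maximum
−19.5%).

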