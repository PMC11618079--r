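Package: migenergy
Title: Energy Budgets of Partial Migration from Heart-Rate and Body-Temperature Biologging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for bio-logger studies of partial migration in
    small birds. Provides a synthetic-data generator for populations of migrant
    and resident individuals with 30-min heart-rate (f_H) and core body
    temperature (T_b) series, quality-index error calibration and filtering,
    gradient-boosted classification of nocturnal migratory flight and derivation
    of departure/arrival/stopover events, calendar-season and event-centred
    staging with pseudoreplication-free resident-to-migrant pairing, linear
    mixed-model and penalized-spline comparisons, a one-node biophysical
    heat-balance model of thermoregulatory expenditure driven by observed T_b
    and ambient temperature under micro-climate scenario grids, and allometric
    flight-cost accounting of thermoregulatory savings versus migration costs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    xgboost,
    pROC,
    mgcv,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
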