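#' Allometric flight power
#'
#' Power required for flapping flight, y = 52.6 M^0.74 watts with body mass
#' M in kilograms (interspecific allometry for birds).
#'
#' @param mass_kg body mass (kg), > 0.
#' @return watts.
#' @export
flight_power <- function(mass_kg) {
  if (any(!is.finite(mass_kg)) || any(mass_kg <= 0)) {
    stop("body mass must be positive")
  }
  52.6 * mass_kg^0.74
}

#' Flight energy from classified flight intervals
#'
#' Total migratory flight energy: allometric flight power times the summed
#' flight duration. Durations come from classified 30-min flight intervals.
#'
#' @param mass_kg body mass (kg).
#' @param n_intervals number of flight-labelled measurement intervals.
#' @param interval_s seconds per interval (default 1800).
#' @return kJ.
#' @export
flight_energy <- function(mass_kg, n_intervals, interval_s = 1800) {
  if (n_intervals == 0) return(0)
  flight_power(mass_kg) * n_intervals * interval_s / 1000
}

#' Estimate per-bird flight interval counts from classified measurements
#'
#' Quality filtering removes a share of the f_H measurements, so counting
#' flight-labelled intervals directly would understate flight duration. On
#' each called flight night, the flight fraction among the kept intervals
#' (an unbiased estimate of the true nightly flight fraction) is scaled by
#' the full number of nocturnal grid intervals of that night taken from the
#' unfiltered record set (T_b is retained for every interval).
#'
#' @param classified classified nocturnal measurements (post-filter).
#' @param all_records unfiltered records (for the per-night grid size).
#' @param night_fraction calling threshold, as in [aggregate_nights()].
#' @return data.frame bird_id, n_intervals (estimated flight intervals).
#' @export
estimate_flight_intervals <- function(classified, all_records,
                                      night_fraction = 0.25) {
  calls <- aggregate_nights(classified, "flight_label", night_fraction)
  fl <- calls[calls$call == "flight", , drop = FALSE]
  grid <- data.table::as.data.table(all_records)
  grid <- grid[grid$is_night]
  grid[, night_date := night_date(timestamp)]
  sizes <- grid[, .N, by = c("bird_id", "night_date")]
  m <- merge(data.table::as.data.table(fl), sizes,
             by = c("bird_id", "night_date"), all.x = TRUE)
  m[is.na(N), N := n_intervals]
  out <- m[, list(n_intervals = sum(flight_fraction * N)), by = "bird_id"]
  as.data.frame(out)
}

#' Thermoregulatory savings between strategies
#'
#' Difference and fold ratio of mean per-bird cumulative thermoregulatory
#' energy (total metabolic power floored at basal) between residents and
#' migrants over a window.
#'
#' @param ledger combined ledger from [population_thermo_ledgers()].
#' @param metadata bird metadata with strategy.
#' @param window optional Date pair restricting the accounting window
#'   (default: the whole ledger; typically the migrant-absence period).
#' @return list(delta_kJ, fold, resident_kJ, migrant_kJ, per_bird).
#' @export
strategy_savings <- function(ledger, metadata, window = NULL) {
  d <- ledger
  if (!is.null(window)) {
    dd <- as.Date(d$timestamp, tz = "UTC")
    d <- d[dd >= as.Date(window[1]) & dd <= as.Date(window[2]), , drop = FALSE]
  }
  per_bird <- stats::aggregate(list(kJ = d$total_W * 1800 / 1000),
                               by = list(bird_id = d$bird_id), FUN = sum)
  per_bird$strategy <- metadata$strategy[match(per_bird$bird_id, metadata$bird_id)]
  if (length(unique(per_bird$strategy)) < 2) {
    stop("ledger must contain both strategies")
  }
  res <- mean(per_bird$kJ[per_bird$strategy == "resident"])
  mig <- mean(per_bird$kJ[per_bird$strategy == "migrant"])
  list(delta_kJ = res - mig, fold = res / mig,
       resident_kJ = res, migrant_kJ = mig, per_bird = per_bird)
}

#' Flight cost as a fraction of thermoregulatory savings
#'
#' Central estimate: mean per-migrant flight energy over the savings of the
#' central scenario, in percent; the range spans the scenario grid.
#' Scenarios with non-positive savings are flagged and excluded from the
#' range with a warning.
#'
#' @param flight_kJ per-migrant flight energies (kJ).
#' @param savings_grid data.frame with columns scenario and delta_kJ, one row
#'   per scenario.
#' @param central_scenario label of the central scenario (default the first
#'   row).
#' @return list(central_pct, min_pct, max_pct, excluded_scenarios).
#' @export
flight_fraction <- function(flight_kJ, savings_grid,
                            central_scenario = savings_grid$scenario[1]) {
  bad <- savings_grid$delta_kJ <= 0
  if (any(bad)) {
    warning("non-positive savings in scenarios: ",
            paste(savings_grid$scenario[bad], collapse = ", "))
  }
  ok <- savings_grid[!bad, , drop = FALSE]
  if (!central_scenario %in% ok$scenario) {
    stop("central scenario has non-positive savings")
  }
  mf <- mean(flight_kJ)
  pct <- 100 * mf / ok$delta_kJ
  list(central_pct = 100 * mf / ok$delta_kJ[ok$scenario == central_scenario],
       min_pct = min(pct), max_pct = max(pct),
       excluded_scenarios = savings_grid$scenario[bad])
}

#' Seasonal trend in thermoregulatory expenditure by strategy
#'
#' Hierarchical penalized-spline model of daily per-bird thermoregulatory
#' energy against Julian day, with a thin-plate smooth per wintering strategy
#' and a random intercept per bird. Returns the per-strategy smooths with
#' 95% confidence bands and the maximal Julian-day windows where the bands do
#' not overlap.
#'
#' @param ledger combined ledger for one scenario.
#' @param metadata bird metadata with strategy.
#' @param k spline basis size.
#' @param min_birds minimum birds per strategy (default 3).
#' @return list(model, daily, smooths, windows).
#' @export
fit_thermo_trend <- function(ledger, metadata, k = 20, min_birds = 3) {
  dt <- data.table::as.data.table(ledger)
  dt[, day := as.Date(timestamp, tz = "UTC")]
  daily <- dt[, list(kJ = sum(total_W * 1800 / 1000)),
              by = c("bird_id", "day")]
  daily[, strategy := metadata$strategy[match(bird_id, metadata$bird_id)]]
  daily <- as.data.frame(daily)
  nb <- tapply(daily$bird_id, daily$strategy, function(x) length(unique(x)))
  if (length(nb) < 2 || any(nb < min_birds)) {
    stop("need at least ", min_birds, " birds per strategy")
  }
  # continuous day index across the logger year (Julian day of the series)
  daily$jday <- as.numeric(daily$day - min(daily$day)) + 1
  daily$strategy <- factor(daily$strategy, levels = c("resident", "migrant"))
  daily$bird_id <- factor(daily$bird_id)
  k_use <- min(k, length(unique(daily$jday)) - 1)
  fit <- mgcv::gam(kJ ~ strategy + s(jday, by = strategy, bs = "tp", k = k_use) +
                     s(bird_id, bs = "re"),
                   data = daily, method = "REML")
  grid <- sort(unique(daily$jday))
  smooths <- do.call(rbind, lapply(levels(daily$strategy), function(s) {
    nd <- data.frame(jday = grid,
                     strategy = factor(s, levels(daily$strategy)),
                     bird_id = daily$bird_id[1])
    pr <- mgcv::predict.gam(fit, nd, se.fit = TRUE, exclude = "s(bird_id)",
                            newdata.guaranteed = TRUE)
    data.frame(jday = grid, day = min(daily$day) + grid - 1, strategy = s,
               fit = as.numeric(pr$fit),
               lo = as.numeric(pr$fit - 1.96 * pr$se.fit),
               hi = as.numeric(pr$fit + 1.96 * pr$se.fit))
  }))
  r <- smooths[smooths$strategy == "resident", ]
  m <- smooths[smooths$strategy == "migrant", ]
  bands <- data.frame(x = r$jday, lo1 = r$lo, hi1 = r$hi,
                      lo2 = m$lo, hi2 = m$hi)
  list(model = fit, daily = daily, smooths = smooths,
       windows = ci_nonoverlap_windows(bands))
}
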