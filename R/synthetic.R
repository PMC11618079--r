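#' Simulation configuration for a partially migratory bio-logger population
#'
#' Bundles every tunable of the synthetic-data generator. Defaults describe a
#' partially migratory blackbird population carrying implanted heart-rate
#' (f_H) and body-temperature (T_b) loggers sampling every 30 min over one
#' logger year (1 September to 10 April). Effect magnitudes are the ones the
#' downstream analyses are built to recover: a nocturnal pre-departure f_H
#' ramp starting 28 days before fall departure reaching -19.5%, flight-night
#' elevations of +199 bpm f_H and +1.23 degC T_b, a ~5.7 degC warmer
#' wintering site, a +0.18 degC migrant-minus-resident winter T_b contrast
#' (implemented as a resident winter decline), and a post-arrival f_H
#' recovery dip lasting up to eight days.
#'
#' Baseline nocturnal/diurnal means are configuration inputs, not literature
#' claims: the nocturnal f_H mean of 374 bpm is back-derived from the flight
#' elevation (+199 bpm being 53.2% of baseline).
#'
#' @param n_residents,n_migrants number of birds per wintering strategy.
#' @param season_start,season_end first and last day of the logger year.
#' @param cadence_min sampling cadence in minutes (must divide 24 h).
#' @param latitude breeding-site latitude, drives the daylength sinusoid.
#' @param breeding_ta list: annual_mean, seasonal_amp, diel_amp (degC),
#'   phi (hourly AR1), sd (degC) for the breeding-site air temperature;
#'   optional spatial_cor (default 0.7) correlates the wintering-site weather
#'   noise with the breeding site's (shared synoptic-scale systems).
#' @param winter_offset mean wintering-minus-breeding air-temperature
#'   difference (degC) over the winter.
#' @param winter_quantile_spread half-width (degC) between the wintering
#'   mean series and its 25th/75th quantile series.
#' @param fh list: nocturnal_mean, diurnal_mean (bpm), indiv_sd (between-bird
#'   intercept sd), phi, sd (AR1 residual).
#' @param tb list: nocturnal_mean, diurnal_mean (degC), resident_winter_decline
#'   (degC, subtracted from residents over the midwinter decline_window,
#'   default "11-15".."02-28" month-days, while migrants sit at warmer
#'   wintering sites), indiv_sd, phi, sd.
#' @param predeparture list: ramp_days (onset before fall departure),
#'   max_reduction (fractional nocturnal f_H reduction reached at departure).
#' @param flight list: delta_fh (bpm), delta_tb (degC), bout_hours_min/max
#'   (flight bout duration per migration night, from dusk).
#' @param recovery list: delta_fh (bpm, negative), duration_days after winter
#'   arrival.
#' @param phenology list: fall_window, spring_window (date pairs for
#'   departures), nights_min/mean/max per journey, stopover_mean (expected
#'   total stopover nights per journey).
#' @param qi list: probs (per-class corruption probability), class_weights
#'   (marginal class frequencies), kernel (multiplicative corruption factors),
#'   truth_every (records between raw-ECG truth subsamples; 120 is 60 h at
#'   30-min cadence).
#' @param seed integer seed making the whole generation deterministic.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_residents = 12,
                       n_migrants = 8,
                       season_start = "2021-09-01",
                       season_end = "2022-04-10",
                       cadence_min = 30,
                       latitude = 47.7,
                       breeding_ta = list(annual_mean = 9, seasonal_amp = 8.5,
                                          diel_amp = 4, phi = 0.8, sd = 1.2),
                       winter_offset = 5.7,
                       winter_quantile_spread = 2.0,
                       fh = list(nocturnal_mean = 374, diurnal_mean = 520,
                                 indiv_sd = 15, phi = 0.6, sd = 12),
                       tb = list(nocturnal_mean = 40.0, diurnal_mean = 42.0,
                                 resident_winter_decline = 0.18,
                                 indiv_sd = 0.15, phi = 0.5, sd = 0.12),
                       predeparture = list(ramp_days = 28, max_reduction = 0.195),
                       flight = list(delta_fh = 199, delta_tb = 1.23,
                                     bout_hours_min = 4, bout_hours_max = 8),
                       recovery = list(delta_fh = -30, duration_days = 8),
                       phenology = list(fall_window = c("2021-10-05", "2021-11-20"),
                                        spring_window = c("2022-03-01", "2022-03-20"),
                                        nights_min = 1, nights_mean = 4,
                                        nights_max = 9, stopover_mean = 2),
                       qi = list(probs = c(0.02, 0.08, 0.20, 0.50),
                                 class_weights = c(0.4, 0.3, 0.2, 0.1),
                                 kernel = c(0.5, 2),
                                 truth_every = 120),
                       seed = 1) {
  cfg <- list(
    n_residents = n_residents, n_migrants = n_migrants,
    season_start = as.Date(season_start), season_end = as.Date(season_end),
    cadence_min = cadence_min, latitude = latitude,
    breeding_ta = breeding_ta, winter_offset = winter_offset,
    winter_quantile_spread = winter_quantile_spread,
    fh = fh, tb = tb, predeparture = predeparture, flight = flight,
    recovery = recovery, phenology = phenology, qi = qi, seed = seed
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_residents >= 0, cfg$n_migrants >= 0,
    cfg$n_residents + cfg$n_migrants > 0,
    cfg$season_start < cfg$season_end,
    (24 * 60) %% cfg$cadence_min == 0,
    cfg$predeparture$max_reduction > 0, cfg$predeparture$max_reduction < 1,
    cfg$phenology$nights_min >= 1,
    cfg$phenology$nights_min <= cfg$phenology$nights_mean,
    cfg$phenology$nights_mean <= cfg$phenology$nights_max,
    all(cfg$qi$probs >= 0), all(cfg$qi$probs <= 1),
    length(cfg$qi$probs) == length(cfg$qi$class_weights)
  )
  fw <- as.Date(cfg$phenology$fall_window)
  sw <- as.Date(cfg$phenology$spring_window)
  if (!(fw[1] <= fw[2] && sw[1] <= sw[2] && fw[2] < sw[1])) {
    stop("invalid migration windows: fall window must precede spring window")
  }
  invisible(cfg)
}

#' Generate a bird population with ground-truth migration events
#'
#' Draws individual metadata (sex, strategy, body mass, tag masses) and, for
#' migrants, a full migration phenology: fall departure within the configured
#' window, a discrete number of flight nights per journey (bounded between
#' the configured minimum and maximum, with the configured mean), stopover
#' nights between flights, winter arrival the day after the last fall flight,
#' and a symmetric spring journey. Residents have no events.
#'
#' @param config a [sim_config()].
#' @return list with `metadata` (data.frame: bird_id, sex, strategy,
#'   body_mass_kg, transmitter_mass_g, logger_id) and `truth`, a
#'   `migration_truth` list holding `events` (per-migrant dates) and `nights`
#'   (flight nights with bout durations).
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_residents + config$n_migrants
  strategy <- c(rep("resident", config$n_residents),
                rep("migrant", config$n_migrants))
  metadata <- data.frame(
    bird_id = sprintf("B%03d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    strategy = strategy,
    body_mass_kg = pmax(0.06, stats::rnorm(n, 0.090, 0.006)),
    transmitter_mass_g = stats::runif(n, 1.8, 2.6),
    logger_id = sprintf("L%03d", seq_len(n)),
    stringsAsFactors = FALSE
  )

  ph <- config$phenology
  fall_days <- seq(as.Date(ph$fall_window[1]), as.Date(ph$fall_window[2]), by = "day")
  spring_days <- seq(as.Date(ph$spring_window[1]), as.Date(ph$spring_window[2]), by = "day")
  p_n <- (ph$nights_mean - ph$nights_min) / max(1, ph$nights_max - ph$nights_min)

  ev_list <- list()
  night_list <- list()
  for (b in metadata$bird_id[metadata$strategy == "migrant"]) {
    jf <- draw_journey(fall_days, ph, p_n,
                       latest_end = as.Date(ph$spring_window[1]) - 14,
                       bout_range = c(config$flight$bout_hours_min,
                                      config$flight$bout_hours_max))
    js <- draw_journey(spring_days, ph, p_n,
                       latest_end = config$season_end - 8,
                       bout_range = c(config$flight$bout_hours_min,
                                      config$flight$bout_hours_max))
    ev_list[[b]] <- data.frame(
      bird_id = b,
      fall_departure = jf$nights[1],
      winter_arrival = jf$nights[length(jf$nights)] + 1,
      spring_departure = js$nights[1],
      spring_arrival = js$nights[length(js$nights)] + 1
    )
    night_list[[b]] <- rbind(
      data.frame(bird_id = b, night_date = jf$nights, season = "fall",
                 bout_hours = jf$bout_hours),
      data.frame(bird_id = b, night_date = js$nights, season = "spring",
                 bout_hours = js$bout_hours)
    )
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(bird_id = character(0), fall_departure = as.Date(character(0)),
               winter_arrival = as.Date(character(0)),
               spring_departure = as.Date(character(0)),
               spring_arrival = as.Date(character(0)))
  nights <- if (length(night_list)) do.call(rbind, night_list) else
    data.frame(bird_id = character(0), night_date = as.Date(character(0)),
               season = character(0), bout_hours = numeric(0))
  rownames(events) <- rownames(nights) <- NULL
  truth <- structure(list(events = events, nights = nights),
                     class = "migration_truth")
  list(metadata = metadata, truth = truth)
}

# one journey: departure date, flight nights separated by Poisson stopover
# runs, compressed if it would overrun latest_end
draw_journey <- function(window_days, ph, p_n, latest_end, bout_range) {
  n_nights <- ph$nights_min +
    stats::rbinom(1, ph$nights_max - ph$nights_min, p_n)
  dep <- window_days[sample.int(length(window_days), 1)]
  gaps <- if (n_nights > 1) {
    stats::rpois(n_nights - 1, ph$stopover_mean / (n_nights - 1))
  } else integer(0)
  nights <- dep + cumsum(c(0, gaps + 1))
  if (nights[length(nights)] > latest_end) {
    nights <- dep + seq_len(n_nights) - 1     # drop stopovers
    overrun <- as.integer(nights[length(nights)] - latest_end)
    if (overrun > 0) nights <- nights - overrun
  }
  list(nights = nights,
       bout_hours = stats::runif(n_nights, bout_range[1], bout_range[2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate ambient-temperature series for breeding and wintering sites
#'
#' Hourly air temperature for four sites: the breeding site and the wintering
#' site at its mean, 25th- and 75th-quantile series. The breeding series is a
#' seasonal + diel sinusoid with AR(1) weather noise; the wintering mean is
#' the same deterministic seasonal shape shifted upward by `winter_offset`
#' with independent weather noise, and the quantile series are pointwise
#' offsets of the mean so q25 <= mean <= q75 everywhere.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns site, timestamp, T_a_C.
#' @export
generate_ambient_series <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  ts <- seq(
    as.POSIXct(paste(config$season_start, "00:00:00"), tz = "UTC"),
    as.POSIXct(paste(config$season_end, "23:00:00"), tz = "UTC"),
    by = 3600
  )
  p <- config$breeding_ta
  lt <- as.POSIXlt(ts, tz = "UTC")
  doy <- lt$yday + 1
  hr <- lt$hour
  det <- p$annual_mean + p$seasonal_amp * cos(2 * pi * (doy - 205) / 365.25) +
    (p$diel_amp / 2) * cos(2 * pi * (hr - 15) / 24)
  noise_b <- ar1_noise(length(ts), p$phi, p$sd)
  # wintering weather shares the synoptic-scale signal of the breeding site
  rho <- p$spatial_cor %||% 0.7
  noise_w <- rho * noise_b + sqrt(1 - rho^2) * ar1_noise(length(ts), p$phi, p$sd)
  breeding <- det + noise_b
  wint_mean <- det + config$winter_offset + noise_w
  rbind(
    data.frame(site = "breeding", timestamp = ts, T_a_C = breeding),
    data.frame(site = "wintering_mean", timestamp = ts, T_a_C = wint_mean),
    data.frame(site = "wintering_q25", timestamp = ts,
               T_a_C = wint_mean - config$winter_quantile_spread),
    data.frame(site = "wintering_q75", timestamp = ts,
               T_a_C = wint_mean + config$winter_quantile_spread)
  )
}

#' Population-level migrant-absence window
#'
#' The period during which migrants are away from the breeding site: from the
#' first fall departure to the last spring arrival across all migrants.
#'
#' @param events data.frame of per-migrant event dates (or a
#'   `migration_truth`).
#' @return Date vector of length 2, or NULL when there are no migrants.
#' @export
absence_window <- function(events) {
  if (is.list(events) && !is.data.frame(events) && !is.null(events$events)) {
    events <- events$events
  }
  if (nrow(events) == 0 || all(is.na(events$fall_departure))) return(NULL)
  c(min(events$fall_departure, na.rm = TRUE),
    max(c(events$spring_arrival, events$winter_arrival), na.rm = TRUE))
}

#' Generate clean bio-logger series for every bird
#'
#' Builds the latent (noise-free of measurement corruption) 30-min heart-rate
#' and body-temperature series per bird. f_H is a day/night baseline plus an
#' individual intercept and AR(1) residual, multiplied at night by the
#' pre-departure ramp for future migrants, with additive flight elevations on
#' migration nights and a decaying post-arrival recovery dip. T_b is built
#' the same way, with a resident decline while migrants are off-site (the
#' warmer wintering sites let migrants hold a slightly higher winter T_b) and
#' a flight elevation.
#'
#' @param metadata,truth output of [generate_population()].
#' @param ambient output of [generate_ambient_series()] (coverage checked;
#'   the physiological series do not otherwise depend on it).
#' @param config a [sim_config()].
#' @return data.frame of clean records: bird_id, logger_id, timestamp,
#'   f_H_bpm, T_b_C, is_night, is_flight (ground-truth flag).
#' @export
generate_biologger_series <- function(metadata, truth, ambient, config) {
  validate_sim_config(config)
  rng <- range(ambient$timestamp)
  if (as.Date(rng[1]) > config$season_start || as.Date(rng[2]) < config$season_end) {
    stop(sprintf("ambient series does not cover the season (%s..%s vs %s..%s)",
                 rng[1], rng[2], config$season_start, config$season_end))
  }
  set.seed(config$seed + 2L)
  grid <- halfhour_grid(config$season_start, config$season_end, config$cadence_min)
  night <- is_night_time(grid, config$latitude)
  ndate <- night_date(grid)
  date <- as.Date(grid, tz = "UTC")
  absent <- absence_window(truth)

  out <- vector("list", nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    md <- metadata[i, ]
    b_fh <- stats::rnorm(1, 0, config$fh$indiv_sd)
    b_tb <- stats::rnorm(1, 0, config$tb$indiv_sd)
    fh_base <- ifelse(night, config$fh$nocturnal_mean, config$fh$diurnal_mean) +
      b_fh + ar1_noise(length(grid), config$fh$phi, config$fh$sd)
    tb_base <- ifelse(night, config$tb$nocturnal_mean, config$tb$diurnal_mean) +
      b_tb + ar1_noise(length(grid), config$tb$phi, config$tb$sd)

    ramp <- numeric(length(grid))
    flight <- rep(FALSE, length(grid))
    rec <- numeric(length(grid))
    if (md$strategy == "migrant") {
      ev <- truth$events[truth$events$bird_id == md$bird_id, ]
      nt <- truth$nights[truth$nights$bird_id == md$bird_id, ]
      d2d <- as.numeric(ev$fall_departure - date)
      on_ramp <- night & d2d >= 1 & d2d <= config$predeparture$ramp_days
      ramp[on_ramp] <- config$predeparture$max_reduction *
        (config$predeparture$ramp_days - d2d[on_ramp]) /
        config$predeparture$ramp_days
      for (k in seq_len(nrow(nt))) {
        idx <- which(night & ndate == nt$night_date[k])
        if (length(idx)) {
          take <- seq_len(min(length(idx), ceiling(nt$bout_hours[k] * 60 / config$cadence_min)))
          flight[idx[take]] <- TRUE
        }
      }
      dsa <- as.numeric(date - ev$winter_arrival)
      in_rec <- dsa >= 0 & dsa < config$recovery$duration_days
      rec[in_rec] <- config$recovery$delta_fh *
        (1 - dsa[in_rec] / config$recovery$duration_days)
    }
    fh <- fh_base * (1 - ramp) + config$flight$delta_fh * flight + rec
    tb <- tb_base + config$flight$delta_tb * flight
    if (md$strategy == "resident") {
      # cold-driven set-point decline over the midwinter months, while
      # migrants sit at warmer wintering sites
      dw <- config$tb$decline_window %||% c("11-15", "02-28")
      md_date <- format(date, "%m-%d")
      in_decline <- if (dw[1] > dw[2]) md_date >= dw[1] | md_date <= dw[2] else
        md_date >= dw[1] & md_date <= dw[2]
      tb[in_decline] <- tb[in_decline] - config$tb$resident_winter_decline
    }
    out[[i]] <- data.frame(
      bird_id = md$bird_id, logger_id = md$logger_id, timestamp = grid,
      f_H_bpm = fh, T_b_C = tb, is_night = night, is_flight = flight,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Corrupt clean records through the quality-index measurement model
#'
#' Assigns each record a QI class, corrupts heart rate with the class-specific
#' probability by multiplying the true bpm by a kernel factor (default halving
#' or doubling, mimicking missed or double-counted ECG peaks), and flags
#' periodic raw-ECG truth subsamples (every `truth_every`-th record per
#' logger) that retain the clean value in `true_fH_bpm`. Body temperature is
#' never corrupted (the sensor is factory-calibrated).
#'
#' @param records clean records from [generate_biologger_series()].
#' @param qi_model list with probs, class_weights, kernel, truth_every.
#' @param seed integer.
#' @return records with added columns qi_class, has_ecg_truth, true_fH_bpm
#'   (NA off the truth subsample) and corrupted f_H_bpm.
#' @export
corrupt_with_qi <- function(records, qi_model, seed = 1) {
  if (any(qi_model$probs < 0 | qi_model$probs > 1)) {
    stop("corruption probabilities must lie in [0, 1]")
  }
  set.seed(seed)
  n <- nrow(records)
  ord <- order(records$logger_id, records$timestamp)
  records <- records[ord, , drop = FALSE]
  k <- length(qi_model$probs)
  qi <- sample.int(k, n, replace = TRUE, prob = qi_model$class_weights)
  corrupted <- stats::runif(n) < qi_model$probs[qi]
  factor <- sample(qi_model$kernel, n, replace = TRUE)
  clean_fh <- records$f_H_bpm
  records$qi_class <- qi
  records$f_H_bpm <- ifelse(corrupted, clean_fh * factor, clean_fh)
  idx_in_logger <- stats::ave(seq_len(n), records$logger_id, FUN = seq_along)
  truthy <- (idx_in_logger - 1L) %% qi_model$truth_every == 0L
  records$has_ecg_truth <- truthy
  records$true_fH_bpm <- ifelse(truthy, clean_fh, NA_real_)
  rownames(records) <- NULL
  records
}

#' Run the full generator
#'
#' Convenience wrapper: population, ambient series, clean records and
#' QI-corrupted records from one configuration.
#'
#' @param config a [sim_config()].
#' @return list(metadata, truth, ambient, clean, records).
#' @export
simulate_dataset <- function(config) {
  pop <- generate_population(config)
  ambient <- generate_ambient_series(config)
  clean <- generate_biologger_series(pop$metadata, pop$truth, ambient, config)
  records <- corrupt_with_qi(clean, config$qi, seed = config$seed + 3L)
  list(metadata = pop$metadata, truth = pop$truth, ambient = ambient,
       clean = clean, records = records)
}
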