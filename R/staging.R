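#' Calendar season definition
#'
#' Month-day windows (inclusive) for the three calendar seasons used in the
#' strategy comparisons: a one-week fall window while both strategies share
#' the breeding site, the 46-day core winter between the last fall and first
#' spring migration events, and the short post-migration spring window that
#' ends when the migrant sample size collapses.
#'
#' @param fall,winter,spring character month-day pairs "MM-DD" (inclusive).
#' @return list of class `season_definition`.
#' @export
season_definition <- function(fall = c("09-01", "09-07"),
                              winter = c("12-03", "01-17"),
                              spring = c("04-02", "04-10")) {
  structure(list(fall = fall, winter = winter, spring = spring),
            class = "season_definition")
}

#' Season window lengths
#'
#' Day counts of the configured windows: inclusive day counts for each
#' season, plus the spring span expressed as the difference between its end
#' and start dates (the convention under which the 2-10 April window spans
#' 8 days).
#'
#' @param definition a [season_definition()].
#' @return list(fall_days, winter_days, spring_days, spring_span).
#' @export
season_lengths <- function(definition = season_definition()) {
  count <- function(md, wrap_year = FALSE) {
    s <- as.Date(paste0("2021-", md[1]))
    e <- as.Date(paste0(if (wrap_year && md[2] < md[1]) "2022-" else "2021-",
                        md[2]))
    as.integer(e - s) + 1L
  }
  list(
    fall_days = count(definition$fall),
    winter_days = count(definition$winter, wrap_year = TRUE),
    spring_days = count(definition$spring),
    spring_span = count(definition$spring) - 1L
  )
}

#' Label records with calendar seasons
#'
#' @param records data.frame with a timestamp column.
#' @param definition a [season_definition()].
#' @return records with added `season` column (fall/winter/spring/none).
#' @export
label_calendar_seasons <- function(records, definition = season_definition()) {
  md <- format(as.Date(records$timestamp, tz = "UTC"), "%m-%d")
  in_window <- function(w) {
    if (w[1] <= w[2]) md >= w[1] & md <= w[2] else md >= w[1] | md <= w[2]
  }
  season <- rep("none", nrow(records))
  season[in_window(definition$fall)] <- "fall"
  season[in_window(definition$winter)] <- "winter"
  season[in_window(definition$spring)] <- "spring"
  records$season <- season
  records
}

#' Event-centred stage windows
#'
#' The eight stages of the migratory life cycle, each anchored on a bird's
#' own events: 35 days of fall pre-migration before fall departure, fall
#' migration/stopover nights between departure and winter arrival, the first
#' 14 days after winter arrival, 21 days of spring pre-migration, spring
#' migration/stopover, and the first 14 days after spring arrival.
#'
#' @param fall_premigration_days,spring_premigration_days,arrival_days window
#'   lengths in days.
#' @return list of class `stage_windows`.
#' @export
stage_windows <- function(fall_premigration_days = 35,
                          spring_premigration_days = 21,
                          arrival_days = 14) {
  structure(list(fall_premigration_days = fall_premigration_days,
                 spring_premigration_days = spring_premigration_days,
                 arrival_days = arrival_days),
            class = "stage_windows")
}

#' Label migrant records with event-centred stages and day offsets
#'
#' Each record of a bird with known events gets the stage whose window covers
#' its date, plus the signed day offset from the stage anchor (departure or
#' arrival day = offset 0; nights are indexed by the date at dusk for the
#' migration/stopover stages). Records outside all windows stay unlabeled
#' (NA). Birds missing an anchor event skip the affected stages with a
#' warning.
#'
#' @param records records for migrant birds.
#' @param events a `migration_events` or `migration_truth` object.
#' @param windows a [stage_windows()].
#' @return records with added `stage` and `day_offset` columns.
#' @export
label_migration_stages <- function(records, events, windows = stage_windows()) {
  ev <- events$events
  nights <- events$nights
  records$stage <- NA_character_
  records$day_offset <- NA_real_
  date <- as.Date(records$timestamp, tz = "UTC")
  ndate <- night_date(records$timestamp)
  for (b in unique(records$bird_id)) {
    sel <- records$bird_id == b
    e <- ev[ev$bird_id == b, ]
    if (nrow(e) == 0) next
    assign_window <- function(anchor, lo, hi, stage) {
      if (is.na(anchor)) {
        warning("bird ", b, ": missing anchor for stage ", stage)
        return()
      }
      off <- as.numeric(date - anchor)
      hit <- sel & off >= lo & off <= hi
      records$stage[hit] <<- stage
      records$day_offset[hit] <<- off[hit]
    }
    # migration vs stopover by per-night type (set first; pre-migration and
    # arrival windows never overlap the journey interval)
    nt <- nights[nights$bird_id == b, , drop = FALSE]
    if (!"type" %in% names(nt)) nt$type <- rep("flight", nrow(nt))
    if (nrow(nt)) {
      for (season in c("fall", "spring")) {
        ns <- nt[nt$season == season, , drop = FALSE]
        if (!nrow(ns)) next
        anchor <- min(ns$night_date)
        hitf <- sel & ndate %in% ns$night_date[ns$type == "flight"]
        records$stage[hitf] <- paste0(season, "_migration")
        records$day_offset[hitf] <- as.numeric(ndate[hitf] - anchor)
        if (any(ns$type == "stopover")) {
          hits <- sel & ndate %in% ns$night_date[ns$type == "stopover"]
          records$stage[hits] <- paste0(season, "_stopover")
          records$day_offset[hits] <- as.numeric(ndate[hits] - anchor)
        }
      }
    }
    assign_window(e$fall_departure, -windows$fall_premigration_days, -1,
                  "fall_premigration")
    assign_window(e$winter_arrival, 0, windows$arrival_days - 1,
                  "winter_arrival")
    assign_window(e$spring_departure, -windows$spring_premigration_days, -1,
                  "spring_premigration")
    assign_window(e$spring_arrival, 0, windows$arrival_days - 1,
                  "spring_arrival")
  }
  records
}

#' Pair resident measurements to simultaneous migrant measurements
#'
#' Each resident measurement is matched to exactly one same-sex migrant
#' measurement sharing its timestamp; residents of a sex are distributed as
#' evenly as possible (round-robin in seeded random order) across the
#' same-sex migrants present at that timestamp, so no resident measurement is
#' ever referenced twice (no pseudoreplication). Migrant measurements with no
#' same-sex resident available stay unpaired and are counted in the report.
#'
#' @param migrant_records,resident_records records on the shared 30-min grid;
#'   migrant records may carry stage labels, which transfer to the pair.
#' @param metadata bird metadata (bird_id, sex, strategy).
#' @param seed integer driving the round-robin start order.
#' @return list: `pairs` (one row per pair with migrant/resident values and
#'   the migrant's stage label) and `report` (n_pairs, n_migrant_unpaired,
#'   n_resident_unused).
#' @export
pair_residents_to_migrants <- function(migrant_records, resident_records,
                                       metadata, seed = 1) {
  sexof <- stats::setNames(metadata$sex, metadata$bird_id)
  mg <- data.table::as.data.table(migrant_records)
  rs <- data.table::as.data.table(resident_records)
  if (nrow(rs) == 0 || nrow(mg) == 0) {
    return(list(pairs = data.frame(),
                report = data.frame(n_pairs = 0L,
                                    n_migrant_unpaired = nrow(mg),
                                    n_resident_unused = nrow(rs))))
  }
  mg[, sex := sexof[bird_id]]
  rs[, sex := sexof[bird_id]]
  set.seed(seed)
  rs <- rs[sample.int(nrow(rs))]          # random order within groups
  data.table::setorderv(mg, c("timestamp", "sex", "bird_id"))
  mg[, slot := seq_len(.N) - 1L, by = c("timestamp", "sex")]
  mg[, n_mig := .N, by = c("timestamp", "sex")]
  rs[, idx := seq_len(.N) - 1L, by = c("timestamp", "sex")]
  # seeded start offset per (timestamp, sex) group
  rs[, grp_start := abs(as.integer(as.numeric(timestamp)) + seed) %% .N,
     by = c("timestamp", "sex")]
  key_m <- paste(mg$timestamp, mg$sex, mg$slot)
  # resident idx maps to migrant slot (idx + grp_start) mod n_mig of its group
  nm <- mg[!duplicated(paste(timestamp, sex)), c("timestamp", "sex", "n_mig")]
  rs <- merge(rs, nm, by = c("timestamp", "sex"), all.x = TRUE, sort = FALSE)
  rs_avail <- rs[!is.na(n_mig)]
  rs_avail[, slot := (idx + grp_start) %% n_mig]
  rs_avail[, rank_in_slot := seq_len(.N) - 1L,
           by = c("timestamp", "sex", "slot")]
  rs_use <- rs_avail[rank_in_slot == 0L]   # one resident per migrant slot
  mm <- match(paste(rs_use$timestamp, rs_use$sex, rs_use$slot), key_m)
  pairs <- data.frame(
    timestamp = rs_use$timestamp,
    sex = rs_use$sex,
    migrant_id = mg$bird_id[mm],
    resident_id = rs_use$bird_id,
    migrant_fH = mg$f_H_bpm[mm],
    resident_fH = rs_use$f_H_bpm,
    migrant_Tb = mg$T_b_C[mm],
    resident_Tb = rs_use$T_b_C,
    is_night = mg$is_night[mm],
    stringsAsFactors = FALSE
  )
  if ("stage" %in% names(mg)) {
    pairs$stage <- mg$stage[mm]
    pairs$day_offset <- mg$day_offset[mm]
  }
  list(pairs = pairs,
       report = data.frame(n_pairs = nrow(pairs),
                           n_migrant_unpaired = nrow(mg) - nrow(pairs),
                           n_resident_unused = nrow(rs) - nrow(pairs)))
}

#' Thin temporal autocorrelation by random per-bird discarding
#'
#' Removes round(fraction * n) records per individual uniformly at random
#' (the established thinning procedure for serially correlated bio-logger
#' series; default 30%).
#'
#' @param records records data.frame with bird_id.
#' @param fraction fraction to discard, in [0, 1).
#' @param seed integer.
#' @return thinned records.
#' @export
thin_autocorrelation <- function(records, fraction = 0.30, seed = 1) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0 || nrow(records) == 0) return(records)
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$bird_id),
                        function(ix) {
                          drop_n <- round(fraction * length(ix))
                          if (drop_n == 0) return(ix)
                          ix[-sample.int(length(ix), drop_n)]
                        }), use.names = FALSE)
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strategy comparison by linear mixed model with Bonferroni post hoc
#'
#' Fits a linear mixed model of the response (f_H or T_b) on wintering
#' strategy crossed with calendar season and day phase, plus sex, with random
#' intercepts for bird identity and date. Post hoc migrant-minus-resident
#' contrasts are computed per season-by-phase cell with Bonferroni-adjusted
#' p-values.
#'
#' @param records labeled, thinned records with columns season, is_night,
#'   sex, strategy and the response.
#' @param response "f_H_bpm" or "T_b_C".
#' @return list: `model` (lmerMod), `contrasts` (data.frame: season, phase,
#'   estimate, SE, df, lower/upper 95% CL, p, p_adjusted), `singular`
#'   (logical).
#' @export
compare_groups_lmm <- function(records, response = c("f_H_bpm", "T_b_C")) {
  response <- match.arg(response)
  d <- records
  d$phase <- ifelse(d$is_night, "night", "day")
  d$date <- factor(as.Date(d$timestamp, tz = "UTC"))
  d$strategy <- factor(d$strategy)
  d$season <- factor(d$season)
  d$y <- d[[response]]
  one_season <- nlevels(droplevels(d$season)) < 2
  one_phase <- length(unique(d$phase)) < 2
  rhs <- paste(c(
    if (one_season && one_phase) "strategy" else
      if (one_season) "strategy * phase" else
        if (one_phase) "strategy * season" else
          "strategy * season * phase",
    if (length(unique(d$sex)) > 1) "sex",
    "(1 | bird_id)", "(1 | date)"
  ), collapse = " + ")
  fit <- lmerTest::lmer(stats::as.formula(paste("y ~", rhs)), data = d)
  singular <- lme4::isSingular(fit)
  spec <- if (one_season && one_phase) ~strategy else
    if (one_season) ~strategy | phase else
      if (one_phase) ~strategy | season else ~strategy | season * phase
  emm <- emmeans::emmeans(fit, spec,
                          lmer.df = "asymptotic",
                          lmerTest.limit = 3)
  # factor levels sort migrant < resident, so the pairwise difference is
  # migrant - resident
  ct <- summary(graphics::pairs(emm), adjust = "bonferroni",
                infer = c(TRUE, TRUE))
  ct <- as.data.frame(ct)
  names(ct)[names(ct) == "asymp.LCL"] <- "lower.CL"
  names(ct)[names(ct) == "asymp.UCL"] <- "upper.CL"
  list(model = fit, contrasts = ct, singular = singular)
}

#' Event-centred strategy comparison with penalized splines
#'
#' For one migratory stage, fits a generalized additive mixed model of the
#' response against the day offset from the stage anchor, with a separate
#' smooth per wintering strategy, sex as a fixed effect and random intercepts
#' for bird and date. Returns the two smooths with 95% confidence bands and
#' the maximal offset windows where the bands do not overlap (the
#' significant-difference windows).
#'
#' @param paired pairs from [pair_residents_to_migrants()], stage-labeled.
#' @param stage stage name to analyse.
#' @param response "fH" or "Tb" (uses the migrant_/resident_ columns).
#' @param night_only restrict to nocturnal pairs (default TRUE).
#' @param min_birds minimum distinct birds per strategy (default 3).
#' @param k spline basis size.
#' @return list: `model`, `smooths` (day_offset, strategy, fit, lo, hi),
#'   `windows` (start, end, sign; sign +1 means migrant above resident).
#' @export
fit_event_centred_gamm <- function(paired, stage, response = c("fH", "Tb"),
                                   night_only = TRUE, min_birds = 3, k = 10) {
  response <- match.arg(response)
  d <- paired[!is.na(paired$stage) & paired$stage == stage, , drop = FALSE]
  if (night_only) d <- d[d$is_night, , drop = FALSE]
  if (nrow(d) == 0) stop("no paired records for stage ", stage)
  long <- rbind(
    data.frame(y = d[[paste0("migrant_", response)]], strategy = "migrant",
               bird_id = d$migrant_id, day_offset = d$day_offset,
               sex = d$sex, date = as.Date(d$timestamp, tz = "UTC")),
    data.frame(y = d[[paste0("resident_", response)]], strategy = "resident",
               bird_id = d$resident_id, day_offset = d$day_offset,
               sex = d$sex, date = as.Date(d$timestamp, tz = "UTC"))
  )
  nb <- tapply(long$bird_id, long$strategy, function(x) length(unique(x)))
  if (any(nb < min_birds)) {
    stop("fewer than ", min_birds, " birds in a strategy; refusing to fit")
  }
  long$strategy <- factor(long$strategy, levels = c("migrant", "resident"))
  long$bird_id <- factor(long$bird_id)
  long$date <- factor(long$date)
  k_use <- min(k, length(unique(long$day_offset)) - 1)
  form <- if (length(unique(long$sex)) > 1) {
    y ~ strategy + sex + s(day_offset, by = strategy, k = k_use) +
      s(bird_id, bs = "re") + s(date, bs = "re")
  } else {
    y ~ strategy + s(day_offset, by = strategy, k = k_use) +
      s(bird_id, bs = "re") + s(date, bs = "re")
  }
  fit <- mgcv::gam(form, data = long, method = "REML")
  grid <- sort(unique(long$day_offset))
  smooths <- do.call(rbind, lapply(levels(long$strategy), function(s) {
    nd <- data.frame(day_offset = grid, strategy = factor(s, levels(long$strategy)),
                     sex = long$sex[1], bird_id = long$bird_id[1],
                     date = long$date[1])
    pr <- mgcv::predict.gam(fit, nd, se.fit = TRUE,
                            exclude = c("s(bird_id)", "s(date)"),
                            newdata.guaranteed = TRUE)
    data.frame(day_offset = grid, strategy = s, fit = as.numeric(pr$fit),
               lo = as.numeric(pr$fit - 1.96 * pr$se.fit),
               hi = as.numeric(pr$fit + 1.96 * pr$se.fit))
  }))
  m <- smooths[smooths$strategy == "migrant", ]
  r <- smooths[smooths$strategy == "resident", ]
  bands <- data.frame(x = m$day_offset, lo1 = m$lo, hi1 = m$hi,
                      lo2 = r$lo, hi2 = r$hi)
  list(model = fit, smooths = smooths, windows = ci_nonoverlap_windows(bands))
}
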