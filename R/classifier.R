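.datatable.aware <- TRUE

CLASSIFIER_FEATURES <- c("f_H_bpm", "T_b_C", "logger_int", "fH_scaled",
                         "Tb_scaled", "fH_diff_mean", "Tb_diff_mean",
                         "Tb_prop_increase")

#' Build classification features from quality-filtered records
#'
#' One feature row per measurement: raw f_H and T_b, the logger identity as
#' an integer category, per-individual z-scores of f_H and T_b, differences
#' from the individual mean, and the proportional T_b change relative to the
#' previous interval. Scaling statistics (mean, sd) are computed on each
#' bird's records before `scale_before` (default: its first 30 days) so that
#' flight intervals do not leak into the baseline. The first interval per
#' bird has no previous value and is dropped.
#'
#' @param records quality-filtered records (bird_id, logger_id, timestamp,
#'   f_H_bpm, T_b_C, is_night, ...).
#' @param scale_before optional Date: scaling statistics use records strictly
#'   before this date; NULL uses each bird's first 30 days.
#' @return data.frame of feature rows (original columns plus features).
#' @export
build_features <- function(records, scale_before = NULL) {
  dt <- data.table::as.data.table(records)
  data.table::setorderv(dt, c("bird_id", "timestamp"))
  n_per <- dt[, .N, by = "bird_id"]
  single <- n_per$bird_id[n_per$N < 2]
  if (length(single)) {
    warning("dropping birds with a single measurement: ",
            paste(single, collapse = ", "))
    dt <- dt[!dt$bird_id %in% single]
  }
  if (nrow(dt) == 0) return(as.data.frame(dt))
  if (is.null(scale_before)) {
    dt[, scale_cut := min(timestamp) + 30 * 86400, by = "bird_id"]
  } else {
    dt[, scale_cut := as.POSIXct(paste(as.Date(scale_before), "00:00:00"),
                                 tz = "UTC")]
  }
  dt[, `:=`(
    fH_mu = mean(f_H_bpm[timestamp < scale_cut]),
    fH_sd = stats::sd(f_H_bpm[timestamp < scale_cut]),
    Tb_mu = mean(T_b_C[timestamp < scale_cut]),
    Tb_sd = stats::sd(T_b_C[timestamp < scale_cut])
  ), by = "bird_id"]
  dt[, `:=`(
    fH_scaled = (f_H_bpm - fH_mu) / ifelse(fH_sd > 0, fH_sd, 1),
    Tb_scaled = (T_b_C - Tb_mu) / ifelse(Tb_sd > 0, Tb_sd, 1),
    fH_diff_mean = f_H_bpm - fH_mu,
    Tb_diff_mean = T_b_C - Tb_mu
  )]
  dt[, Tb_prev := data.table::shift(T_b_C), by = "bird_id"]
  dt[, Tb_prop_increase := (T_b_C - Tb_prev) / Tb_prev]
  dt <- dt[!is.na(Tb_prop_increase)]
  dt[, logger_int := as.integer(factor(logger_id))]
  dt[, c("scale_cut", "fH_mu", "fH_sd", "Tb_mu", "Tb_sd", "Tb_prev") := NULL]
  as.data.frame(dt)
}

#' Train the gradient-boosted flight classifier
#'
#' Boosted decision trees (xgboost, logistic loss) on the feature set,
#' predicting per-measurement migratory flight versus stationary. Labels
#' come from known departure/arrival telemetry or, on synthetic data, the
#' generator's ground truth.
#'
#' @param features output of [build_features()].
#' @param labels logical or 0/1 vector, one per feature row.
#' @param n_trees,max_depth,learning_rate boosting hyperparameters
#'   (defaults 500 trees, depth 3, rate 0.05).
#' @param seed integer; training is single-threaded and deterministic.
#' @return object of class `migration_model`: the booster, feature names and
#'   training AUC.
#' @export
train_migration_model <- function(features, labels, n_trees = 500,
                                  max_depth = 3, learning_rate = 0.05,
                                  seed = 1) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2) {
    stop("labels contain a single class; cannot train a classifier")
  }
  stopifnot(nrow(features) == length(y))
  x <- as.matrix(features[, CLASSIFIER_FEATURES])
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = learning_rate, nthread = 1, seed = seed),
    data = dtrain, nrounds = n_trees, verbose = 0
  )
  p <- stats::predict(booster, x)
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = p,
                                        quiet = TRUE, direction = "<")))
  structure(list(booster = booster, features = CLASSIFIER_FEATURES,
                 training_auc = auc),
            class = "migration_model")
}

#' Predict per-measurement flight probabilities and labels
#'
#' @param model a `migration_model`.
#' @param features feature rows with the training schema.
#' @param threshold probability at or above which a measurement is labelled
#'   flight (default 0.5).
#' @return features with added columns flight_prob and flight_label.
#' @export
classify_measurements <- function(model, features, threshold = 0.5) {
  missing <- setdiff(model$features, names(features))
  if (length(missing)) {
    stop("feature schema mismatch; missing: ", paste(missing, collapse = ", "))
  }
  x <- as.matrix(features[, model$features])
  p <- stats::predict(model$booster, xgboost::xgb.DMatrix(x))
  features$flight_prob <- p
  features$flight_label <- p >= threshold
  features
}

#' Aggregate measurement labels into per-bird-night calls
#'
#' A night (indexed by its date at dusk) is called a flight night when the
#' fraction of its nocturnal measurements labelled flight reaches
#' `night_fraction` (default 0.25; migrating birds rarely fly the whole
#' night, so a quarter of the night suffices for a call).
#'
#' @param labeled data.frame with bird_id, timestamp, is_night and a logical
#'   label column.
#' @param label_col name of the logical flight-label column.
#' @param night_fraction calling threshold on the nightly flight fraction.
#' @return data.frame: bird_id, night_date, n_intervals, flight_fraction,
#'   call ("flight"/"stationary").
#' @export
aggregate_nights <- function(labeled, label_col = "flight_label",
                             night_fraction = 0.25) {
  dt <- data.table::as.data.table(labeled)
  dt <- dt[dt$is_night]
  dt[, night_date := night_date(timestamp)]
  dt[, lab := as.logical(.SD[[1]]), .SDcols = label_col]
  calls <- dt[, list(n_intervals = .N, flight_fraction = mean(lab)),
              by = c("bird_id", "night_date")]
  calls[, call := ifelse(flight_fraction >= night_fraction,
                         "flight", "stationary")]
  data.table::setorderv(calls, c("bird_id", "night_date"))
  as.data.frame(calls)
}

#' Derive migration events from nightly calls
#'
#' Fall departure is the first flight night of the fall window; winter
#' arrival is the day after the last fall flight night; stationary nights in
#' between are stopovers. Spring is symmetric. Birds without flight nights
#' yield empty events.
#'
#' @param night_calls output of [aggregate_nights()].
#' @param season_split Date separating fall from spring journeys (default
#'   "2022-01-01"; flight nights before it are fall, after it spring).
#' @return `migration_events`: list with `events` (one row per bird with any
#'   flight night) and `nights` (flight and stopover nights with season).
#' @export
derive_migration_events <- function(night_calls, season_split = "2022-01-01") {
  season_split <- as.Date(season_split)
  ev_list <- list(); night_list <- list()
  for (b in unique(night_calls$bird_id)) {
    nc <- night_calls[night_calls$bird_id == b, ]
    fl <- sort(nc$night_date[nc$call == "flight"])
    if (!length(fl)) next
    fall <- fl[fl < season_split]
    spring <- fl[fl >= season_split]
    journey <- function(nights, season) {
      if (!length(nights)) {
        return(list(dep = as.Date(NA), arr = as.Date(NA), df = NULL))
      }
      dep <- nights[1]
      arr <- nights[length(nights)] + 1
      all_days <- seq(dep, nights[length(nights)], by = "day")
      stop <- setdiff(all_days, nights)
      df <- rbind(
        data.frame(bird_id = b, night_date = nights, season = season,
                   type = "flight", stringsAsFactors = FALSE),
        if (length(stop)) data.frame(bird_id = b,
                                     night_date = as.Date(stop, origin = "1970-01-01"),
                                     season = season, type = "stopover",
                                     stringsAsFactors = FALSE)
      )
      list(dep = dep, arr = arr, df = df)
    }
    jf <- journey(fall, "fall")
    js <- journey(spring, "spring")
    ev_list[[b]] <- data.frame(
      bird_id = b, fall_departure = jf$dep, winter_arrival = jf$arr,
      spring_departure = js$dep, spring_arrival = js$arr,
      stringsAsFactors = FALSE
    )
    night_list[[b]] <- rbind(jf$df, js$df)
    ok <- c(jf$dep, jf$arr, js$dep, js$arr)
    ok <- ok[!is.na(ok)]
    if (is.unsorted(ok)) {
      warning("bird ", b, ": derived events violate chronological order")
    }
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(bird_id = character(0), fall_departure = as.Date(character(0)),
               winter_arrival = as.Date(character(0)),
               spring_departure = as.Date(character(0)),
               spring_arrival = as.Date(character(0)))
  nights <- if (length(night_list)) do.call(rbind, night_list) else
    data.frame(bird_id = character(0), night_date = as.Date(character(0)),
               season = character(0), type = character(0))
  rownames(events) <- rownames(nights) <- NULL
  structure(list(events = events, nights = nights), class = "migration_events")
}

#' Evaluate the classifier against ground truth
#'
#' Measurement-level AUC of flight probabilities against true flight flags,
#' and night-level percent agreement between called and true flight nights.
#'
#' @param classified output of [classify_measurements()] (needs flight_prob,
#'   flight_label and the truth column `is_flight`).
#' @param night_fraction passed to [aggregate_nights()] for both predicted
#'   and true night calls.
#' @return list(auc, night_agreement_pct, n_measurements, n_nights).
#' @export
evaluate_classifier <- function(classified, night_fraction = 0.25) {
  truth <- as.integer(classified$is_flight)
  auc <- if (length(unique(truth)) < 2) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(response = truth,
                                   predictor = classified$flight_prob,
                                   quiet = TRUE, direction = "<")))
  pred_n <- aggregate_nights(classified, "flight_label", night_fraction)
  true_n <- aggregate_nights(classified, "is_flight", night_fraction)
  m <- merge(pred_n[, c("bird_id", "night_date", "call")],
             true_n[, c("bird_id", "night_date", "call")],
             by = c("bird_id", "night_date"), suffixes = c("_pred", "_true"))
  list(auc = auc,
       night_agreement_pct = 100 * mean(m$call_pred == m$call_true),
       n_measurements = nrow(classified), n_nights = nrow(m))
}
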