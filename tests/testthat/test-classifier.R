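make_feature_records <- function(n_birds = 2, days = 10, seed = 1) {
  set.seed(seed)
  grid <- halfhour_grid("2021-09-01", as.Date("2021-09-01") + days - 1)
  do.call(rbind, lapply(seq_len(n_birds), function(i) {
    data.frame(bird_id = sprintf("B%02d", i), logger_id = sprintf("L%02d", i),
               timestamp = grid, f_H_bpm = stats::rnorm(length(grid), 400, 20),
               T_b_C = stats::rnorm(length(grid), 41, 0.3),
               is_night = is_night_time(grid), is_flight = FALSE,
               stringsAsFactors = FALSE)
  }))
}

test_that("feature construction matches direct formula oracles", {
  r <- make_feature_records(1, days = 10)
  # constant T_b: proportional increase identically zero
  r$T_b_C <- 40
  f <- build_features(r)
  expect_true(all(f$Tb_prop_increase == 0))
  expect_equal(nrow(f), nrow(r) - 1)          # first interval dropped

  # 40.0 -> 40.4 gives exactly 0.01
  r2 <- r[1:2, ]; r2$T_b_C <- c(40.0, 40.4)
  r2 <- rbind(r2, r[3:5, ])
  f2 <- build_features(r2)
  expect_equal(f2$Tb_prop_increase[1], 0.01)

  # hand-built series: z-scores match an independent mean/sd computation
  r3 <- r[1:5, ]
  r3$f_H_bpm <- c(380, 390, 400, 410, 420)
  f3 <- build_features(r3)
  expect_equal(f3$fH_scaled,
               ((r3$f_H_bpm - mean(r3$f_H_bpm)) / stats::sd(r3$f_H_bpm))[-1])
  expect_equal(f3$fH_diff_mean, (r3$f_H_bpm - mean(r3$f_H_bpm))[-1])

  # a single-measurement bird is dropped with a warning
  expect_warning(build_features(rbind(r[1:10, ], {
    x <- r[11, ]; x$bird_id <- "B99"; x
  })), "single measurement")
})

test_that("boosted model separates, collapses on shuffled labels, rejects one class", {
  r <- make_feature_records(2, days = 20, seed = 3)
  # plant a perfectly separable flight signature
  night_idx <- which(r$is_night)
  fl <- sample(night_idx, 400)
  r$is_flight[fl] <- TRUE
  r$f_H_bpm[fl] <- r$f_H_bpm[fl] + 250
  f <- build_features(r)
  m <- train_migration_model(f, f$is_flight, n_trees = 150, seed = 5)
  expect_equal(m$training_auc, 1.0, tolerance = 1e-6)

  set.seed(8)
  shuffled <- sample(f$is_flight)
  m0 <- train_migration_model(f, shuffled, n_trees = 30, seed = 5)
  # training AUC on pure noise stays modest for shallow boosting
  cl0 <- classify_measurements(m0, f)
  ev0 <- pROC::auc(pROC::roc(response = as.integer(shuffled),
                             predictor = cl0$flight_prob, quiet = TRUE,
                             direction = "<"))
  expect_gt(as.numeric(ev0), 0.4)

  expect_error(train_migration_model(f, rep(TRUE, nrow(f))), "single class")

  # thresholds at the extremes
  cl <- classify_measurements(m, f, threshold = 0)
  expect_true(all(cl$flight_label))
  cl2 <- classify_measurements(m, f, threshold = 1 + 1e-9)
  expect_true(all(!cl2$flight_label))
  expect_error(classify_measurements(m, f[, 1:3]), "missing")
})

test_that("night aggregation applies the fraction threshold exactly", {
  ts <- seq(as.POSIXct("2021-10-01 18:00:00", tz = "UTC"), by = 1800,
            length.out = 16)
  base <- data.frame(bird_id = "B01", timestamp = ts, is_night = TRUE)
  base$flight_label <- FALSE
  base$flight_label[1:3] <- TRUE               # 3/16 < 0.25
  expect_equal(aggregate_nights(base)$call, "stationary")
  base$flight_label[4] <- TRUE                 # 4/16 = 0.25
  expect_equal(aggregate_nights(base)$call, "flight")
  base$flight_label <- TRUE
  expect_equal(aggregate_nights(base)$call, "flight")
  base$flight_label <- FALSE
  expect_equal(aggregate_nights(base)$call, "stationary")
})

test_that("event derivation applies the departure/arrival/stopover rules", {
  calls <- data.frame(
    bird_id = "B01",
    night_date = as.Date(c("2021-10-12", "2021-10-13", "2021-10-14",
                           "2021-10-15")),
    n_intervals = 16, flight_fraction = c(1, 0, 1, 1),
    call = c("flight", "stationary", "flight", "flight")
  )
  ev <- derive_migration_events(calls)
  expect_equal(ev$events$fall_departure, as.Date("2021-10-12"))
  expect_equal(ev$events$winter_arrival, as.Date("2021-10-16"))
  expect_equal(ev$nights$night_date[ev$nights$type == "stopover"],
               as.Date("2021-10-13"))

  # no flight nights: empty events
  calls0 <- calls; calls0$call <- "stationary"
  ev0 <- derive_migration_events(calls0)
  expect_equal(nrow(ev0$events), 0)

  # single flight night: departure and arrival one day apart, no stopovers
  calls1 <- calls[1, ]
  ev1 <- derive_migration_events(calls1)
  expect_equal(as.integer(ev1$events$winter_arrival - ev1$events$fall_departure), 1L)
  expect_true(all(ev1$nights$type == "flight"))

  # pure function: rerun yields identical events
  expect_identical(ev, derive_migration_events(calls))
})

test_that("classifier evaluation reports perfect and inverted extremes", {
  ts <- seq(as.POSIXct("2021-10-01 18:00:00", tz = "UTC"), by = 1800,
            length.out = 200)
  d <- data.frame(bird_id = "B01", timestamp = ts, is_night = TRUE,
                  is_flight = rep(c(TRUE, FALSE), each = 100))
  d$flight_prob <- ifelse(d$is_flight, 0.9, 0.1)
  d$flight_label <- d$flight_prob >= 0.5
  ev <- evaluate_classifier(d)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$night_agreement_pct, 100)

  d$flight_prob <- 1 - d$flight_prob
  d$flight_label <- d$flight_prob >= 0.5
  ev2 <- evaluate_classifier(d)
  expect_equal(ev2$auc, 0.0)
})

test_that("events recover truth exactly on noise-free synthetic data", {
  cfg <- sim_config(
    n_residents = 2, n_migrants = 2,
    fh = list(nocturnal_mean = 374, diurnal_mean = 520, indiv_sd = 0,
              phi = 0.6, sd = 0),
    tb = list(nocturnal_mean = 40, diurnal_mean = 42,
              resident_winter_decline = 0.18, indiv_sd = 0, phi = 0.5, sd = 0),
    qi = list(probs = c(0, 0, 0, 0), class_weights = c(0.25, 0.25, 0.25, 0.25),
              kernel = c(0.5, 2), truth_every = 120),
    seed = 31
  )
  sim <- simulate_dataset(cfg)
  f <- build_features(sim$records)
  fn <- f[f$is_night, ]
  m <- train_migration_model(fn, fn$is_flight, n_trees = 100, seed = 31)
  cl <- classify_measurements(m, fn)
  ev <- derive_migration_events(aggregate_nights(cl))
  truth_ev <- sim$truth$events[order(sim$truth$events$bird_id), ]
  got <- ev$events[order(ev$events$bird_id), ]
  expect_equal(got$fall_departure, truth_ev$fall_departure)
  expect_equal(got$spring_arrival, truth_ev$spring_arrival)
})
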