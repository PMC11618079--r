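rec_at <- function(dates, bird = "B01") {
  data.frame(bird_id = bird,
             timestamp = as.POSIXct(paste(dates, "12:00:00"), tz = "UTC"))
}

test_that("calendar season labels follow the defined windows", {
  r <- rec_at(c("2021-09-05", "2021-12-20", "2022-01-10", "2022-02-01",
                "2022-04-05", "2021-09-08"))
  out <- label_calendar_seasons(r)
  expect_equal(out$season,
               c("fall", "winter", "winter", "none", "spring", "none"))
})

test_that("season window day counts match the study definitions", {
  len <- season_lengths()
  expect_identical(len$winter_days, 46L)
  expect_identical(len$spring_span, 8L)
  expect_identical(len$fall_days, 7L)
})

test_that("stage labels carry the right windows and signed day offsets", {
  ev <- structure(list(
    events = data.frame(bird_id = "B01",
                        fall_departure = as.Date("2021-10-20"),
                        winter_arrival = as.Date("2021-10-26"),
                        spring_departure = as.Date("2022-03-10"),
                        spring_arrival = as.Date("2022-03-16")),
    nights = data.frame(bird_id = "B01",
                        night_date = as.Date(c("2021-10-20", "2021-10-22",
                                               "2021-10-25")),
                        season = "fall", type = c("flight", "flight", "flight"))
  ), class = "migration_events")
  r <- rec_at(c("2021-10-10", "2021-09-14", "2021-11-08", "2022-03-01",
                "2022-03-29"))
  out <- label_migration_stages(r, ev)
  expect_equal(out$stage[1], "fall_premigration")
  expect_equal(out$day_offset[1], -10)
  expect_true(is.na(out$stage[2]))             # 36 days out: outside window
  expect_equal(out$stage[3], "winter_arrival") # arrival day + 13
  expect_equal(out$day_offset[3], 13)
  expect_equal(out$stage[4], "spring_premigration")
  expect_equal(out$stage[5], "spring_arrival")
  # stopover night between flights labelled via derived events
  r2 <- rec_at("2021-10-21")
  r2$timestamp <- as.POSIXct("2021-10-21 23:00:00", tz = "UTC")
  ev$nights <- rbind(ev$nights,
                     data.frame(bird_id = "B01",
                                night_date = as.Date("2021-10-21"),
                                season = "fall", type = "stopover"))
  out2 <- label_migration_stages(r2, ev)
  expect_equal(out2$stage, "fall_stopover")
})

test_that("pairing is one-to-one, sex- and timestamp-matched, without reuse", {
  md <- data.frame(bird_id = c("M1", "R1", "R2", "R3"),
                   sex = "F", strategy = c("migrant", rep("resident", 3)))
  ts <- as.POSIXct("2021-12-10 22:00:00", tz = "UTC")
  mig <- data.frame(bird_id = "M1", timestamp = ts, f_H_bpm = 400,
                    T_b_C = 40, is_night = TRUE)
  res <- data.frame(bird_id = c("R1", "R2", "R3"), timestamp = ts,
                    f_H_bpm = c(380, 390, 410), T_b_C = 40, is_night = TRUE)
  out <- pair_residents_to_migrants(mig, res, md, seed = 1)
  expect_equal(nrow(out$pairs), 1)
  expect_equal(out$report$n_resident_unused, 2)

  # 2 migrants, 2 residents: two pairs, each resident once
  md2 <- data.frame(bird_id = c("M1", "M2", "R1", "R2"), sex = "F",
                    strategy = c("migrant", "migrant", "resident", "resident"))
  mig2 <- data.frame(bird_id = c("M1", "M2"), timestamp = ts, f_H_bpm = 400,
                     T_b_C = 40, is_night = TRUE)
  out2 <- pair_residents_to_migrants(mig2, res[1:2, ], md2, seed = 1)
  expect_equal(nrow(out2$pairs), 2)
  expect_equal(sort(out2$pairs$resident_id), c("R1", "R2"))
  expect_equal(sort(out2$pairs$migrant_id), c("M1", "M2"))

  # no residents: empty result
  out3 <- pair_residents_to_migrants(mig, res[0, ], md, seed = 1)
  expect_equal(nrow(out3$pairs), 0)

  # sexes never mix
  md4 <- md; md4$sex <- c("F", "M", "M", "M")
  out4 <- pair_residents_to_migrants(mig, res, md4, seed = 1)
  expect_equal(nrow(out4$pairs), 0)
  expect_equal(out4$report$n_migrant_unpaired, 1)
})

test_that("pairing on a population never reuses a resident measurement", {
  cfg <- sim_config(n_residents = 8, n_migrants = 6, seed = 17)
  sim <- simulate_dataset(cfg)
  recs <- sim$clean
  recs$strategy <- sim$metadata$strategy[match(recs$bird_id, sim$metadata$bird_id)]
  out <- pair_residents_to_migrants(recs[recs$strategy == "migrant", ],
                                    recs[recs$strategy == "resident", ],
                                    sim$metadata, seed = 2)
  p <- out$pairs
  expect_equal(anyDuplicated(paste(p$resident_id, p$timestamp)), 0L)
  sexof <- stats::setNames(sim$metadata$sex, sim$metadata$bird_id)
  expect_true(all(sexof[p$migrant_id] == sexof[p$resident_id]))
  # per-timestamp-and-sex load difference across migrants is at most one
  load <- tapply(p$migrant_id, paste(p$timestamp, p$sex),
                 function(x) { t <- table(x); max(t) - min(t) })
  expect_true(all(load <= 1))
})

test_that("autocorrelation thinning removes the exact per-bird count", {
  r <- do.call(rbind, lapply(c("A", "B"), function(b) {
    d <- rec_at(rep("2021-12-01", 100), bird = b)
    d$timestamp <- d$timestamp + seq_len(100) * 1800
    d
  }))
  expect_identical(thin_autocorrelation(r, fraction = 0), r)
  th <- thin_autocorrelation(r, fraction = 0.30, seed = 1)
  expect_equal(as.vector(table(th$bird_id)), c(70L, 70L))
  th2 <- thin_autocorrelation(r, fraction = 0.30, seed = 2)
  expect_equal(as.vector(table(th2$bird_id)), c(70L, 70L))
  expect_false(identical(th$timestamp, th2$timestamp))
})

test_that("mixed-model contrasts recover injected and null winter effects", {
  cfg <- sim_config(n_residents = 10, n_migrants = 10, seed = 23)
  sim <- simulate_dataset(cfg)
  recs <- label_calendar_seasons(sim$clean)
  recs$strategy <- sim$metadata$strategy[match(recs$bird_id, sim$metadata$bird_id)]
  recs$sex <- sim$metadata$sex[match(recs$bird_id, sim$metadata$bird_id)]
  w <- recs[recs$season == "winter" & recs$is_night, ]
  w <- thin_autocorrelation(w, 0.30, seed = 23)
  fit <- compare_groups_lmm(w, "T_b_C")
  ct <- fit$contrasts
  # migrant - resident winter T_b contrast: positive, near +0.18
  expect_gt(ct$estimate[1], 0)
  expect_true(ct$lower.CL[1] <= 0.18 + 0.12 && ct$upper.CL[1] >= 0.18 - 0.12)
  expect_lt(ct$p.value[1], 0.05)

  # identical groups: estimate near zero
  half <- sim$metadata$bird_id[1:10]
  w0 <- w
  w0$strategy <- ifelse(w0$bird_id %in% sample(unique(w0$bird_id), 10),
                        "A", "B")
  fit0 <- compare_groups_lmm(w0, "f_H_bpm")
  expect_gt(fit0$contrasts$p.value[1], 0.01)
})

test_that("event-centred smooths mirror when strategy labels swap", {
  cfg <- sim_config(n_residents = 6, n_migrants = 6, seed = 29)
  sim <- simulate_dataset(cfg)
  recs <- sim$clean
  recs$strategy <- sim$metadata$strategy[match(recs$bird_id, sim$metadata$bird_id)]
  recs$sex <- sim$metadata$sex[match(recs$bird_id, sim$metadata$bird_id)]
  mig <- label_migration_stages(recs[recs$strategy == "migrant", ], sim$truth)
  pr <- pair_residents_to_migrants(mig, recs[recs$strategy == "resident", ],
                                   sim$metadata, seed = 5)
  g <- fit_event_centred_gamm(pr$pairs, "fall_premigration", "fH")
  sm <- g$smooths
  mean_gap <- mean(sm$fit[sm$strategy == "migrant"]) -
    mean(sm$fit[sm$strategy == "resident"])
  # swap the strategy columns: migrant values become "resident" and vice versa
  swapped <- pr$pairs
  swapped[, c("migrant_fH", "resident_fH")] <-
    swapped[, c("resident_fH", "migrant_fH")]
  swapped[, c("migrant_id", "resident_id")] <-
    swapped[, c("resident_id", "migrant_id")]
  g2 <- fit_event_centred_gamm(swapped, "fall_premigration", "fH")
  sm2 <- g2$smooths
  mean_gap2 <- mean(sm2$fit[sm2$strategy == "migrant"]) -
    mean(sm2$fit[sm2$strategy == "resident"])
  expect_equal(mean_gap, -mean_gap2, tolerance = 1e-6)
  if (nrow(g$windows) > 0) {
    expect_true(all(g$windows$sign == -g2$windows$sign))
  }
  # refuses with too few birds per strategy
  expect_error(fit_event_centred_gamm(pr$pairs, "fall_premigration", "fH",
                                      min_birds = 50), "refusing")
})
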