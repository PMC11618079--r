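test_that("population generation honours counts, phenology bounds and determinism", {
  cfg <- sim_config(n_residents = 2, n_migrants = 1,
                    phenology = list(fall_window = c("2021-10-05", "2021-11-20"),
                                     spring_window = c("2022-03-01", "2022-03-20"),
                                     nights_min = 4, nights_mean = 4,
                                     nights_max = 4, stopover_mean = 2),
                    seed = 1)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop$metadata), 3)
  mig <- pop$metadata$bird_id[pop$metadata$strategy == "migrant"]
  fall_nights <- pop$truth$nights[pop$truth$nights$bird_id == mig &
                                    pop$truth$nights$season == "fall", ]
  expect_equal(nrow(fall_nights), 4)

  # degenerate: no migrants
  cfg0 <- sim_config(n_migrants = 0, seed = 2)
  pop0 <- generate_population(cfg0)
  expect_true(all(pop0$metadata$strategy == "resident"))
  expect_equal(nrow(pop0$truth$events), 0)

  # determinism: identical config and seed give identical output
  pop2 <- generate_population(cfg)
  expect_identical(pop, pop2)

  # chronological ordering of events and transmitter-mass bounds
  cfg3 <- sim_config(n_migrants = 10, seed = 3)
  pop3 <- generate_population(cfg3)
  ev <- pop3$truth$events
  expect_true(all(ev$fall_departure < ev$winter_arrival))
  expect_true(all(ev$winter_arrival < ev$spring_departure))
  expect_true(all(ev$spring_departure < ev$spring_arrival))
  expect_true(all(pop3$metadata$transmitter_mass_g >= 1.8 &
                    pop3$metadata$transmitter_mass_g <= 2.6))
  n_per <- table(pop3$truth$nights$bird_id, pop3$truth$nights$season)
  expect_true(all(n_per >= 1 & n_per <= 9))
})

test_that("invalid migration windows are rejected", {
  expect_error(
    sim_config(phenology = list(fall_window = c("2022-03-01", "2022-03-20"),
                                spring_window = c("2021-10-05", "2021-11-20"),
                                nights_min = 1, nights_mean = 4,
                                nights_max = 9, stopover_mean = 2)),
    "fall window must precede spring"
  )
})

test_that("ambient series reproduce the configured winter offset and quantile order", {
  cfg <- sim_config(seed = 4)
  amb <- generate_ambient_series(cfg)
  d <- as.Date(amb$timestamp, tz = "UTC")
  win <- d >= as.Date("2021-12-03") & d <= as.Date("2022-01-17")
  diff <- mean(amb$T_a_C[amb$site == "wintering_mean" & win]) -
    mean(amb$T_a_C[amb$site == "breeding" & win])
  expect_lt(abs(diff - 5.7), 0.2)

  # quantile series bracket the mean pointwise
  m <- amb$T_a_C[amb$site == "wintering_mean"]
  expect_true(all(amb$T_a_C[amb$site == "wintering_q25"] <= m))
  expect_true(all(amb$T_a_C[amb$site == "wintering_q75"] >= m))

  # zero offset: breeding and wintering means indistinguishable
  cfg0 <- sim_config(winter_offset = 0, seed = 4)
  amb0 <- generate_ambient_series(cfg0)
  diff0 <- mean(amb0$T_a_C[amb0$site == "wintering_mean" & win]) -
    mean(amb0$T_a_C[amb0$site == "breeding" & win])
  expect_lt(abs(diff0), 0.2)

  # zero quantile spread collapses the three wintering series
  cfgq <- sim_config(winter_quantile_spread = 0, seed = 4)
  ambq <- generate_ambient_series(cfgq)
  expect_equal(ambq$T_a_C[ambq$site == "wintering_q25"],
               ambq$T_a_C[ambq$site == "wintering_mean"])
  expect_equal(ambq$T_a_C[ambq$site == "wintering_q75"],
               ambq$T_a_C[ambq$site == "wintering_mean"])
})

test_that("noise-free series carry the exact flight elevations and no spurious ramp", {
  cfg <- sim_config(
    n_residents = 1, n_migrants = 1,
    fh = list(nocturnal_mean = 374, diurnal_mean = 520, indiv_sd = 0,
              phi = 0.6, sd = 0),
    tb = list(nocturnal_mean = 40, diurnal_mean = 42,
              resident_winter_decline = 0, indiv_sd = 0, phi = 0.5, sd = 0),
    seed = 9
  )
  sim <- simulate_dataset(cfg)
  cl <- sim$clean
  res_id <- sim$metadata$bird_id[sim$metadata$strategy == "resident"]
  mig_id <- sim$metadata$bird_id[sim$metadata$strategy == "migrant"]
  fl <- cl[cl$bird_id == mig_id & cl$is_flight, ]
  paired_res <- cl[cl$bird_id == res_id & cl$timestamp %in% fl$timestamp, ]
  expect_equal(mean(fl$f_H_bpm) - mean(paired_res$f_H_bpm), 199, tolerance = 1e-10)
  expect_equal(mean(fl$T_b_C) - mean(paired_res$T_b_C), 1.23, tolerance = 1e-10)

  # near-zero ramp: pre-departure nocturnal means agree across strategies
  cfg2 <- sim_config(
    n_residents = 1, n_migrants = 1,
    fh = list(nocturnal_mean = 374, diurnal_mean = 520, indiv_sd = 0,
              phi = 0.6, sd = 0),
    predeparture = list(ramp_days = 28, max_reduction = 1e-9),
    seed = 9
  )
  sim2 <- simulate_dataset(cfg2)
  cl2 <- sim2$clean
  ev <- sim2$truth$events
  pre <- as.Date(cl2$timestamp, tz = "UTC") < ev$fall_departure &
    as.Date(cl2$timestamp, tz = "UTC") >= ev$fall_departure - 28
  m <- cl2$bird_id == ev$bird_id
  r <- !m
  expect_equal(mean(cl2$f_H_bpm[pre & m & cl2$is_night]),
               mean(cl2$f_H_bpm[pre & r & cl2$is_night]), tolerance = 1e-6)

  # with the default ramp, the migrant nocturnal mean is depressed
  sim3 <- simulate_dataset(cfg)
  cl3 <- sim3$clean
  ev3 <- sim3$truth$events
  pre3 <- as.Date(cl3$timestamp, tz = "UTC") < ev3$fall_departure &
    as.Date(cl3$timestamp, tz = "UTC") >= ev3$fall_departure - 28
  m3 <- cl3$bird_id == ev3$bird_id
  expect_lt(mean(cl3$f_H_bpm[pre3 & m3 & cl3$is_night]),
            mean(cl3$f_H_bpm[pre3 & !m3 & cl3$is_night]) - 10)
})

test_that("winter strategy contrasts at defaults: zero for f_H, +0.18 degC for T_b", {
  cfg <- sim_config(n_residents = 30, n_migrants = 30, seed = 21)
  sim <- simulate_dataset(cfg)
  cl <- label_calendar_seasons(sim$clean)
  cl$strategy <- sim$metadata$strategy[match(cl$bird_id, sim$metadata$bird_id)]
  w <- cl[cl$season == "winter" & cl$is_night & !cl$is_flight, ]
  dm_t <- mean(w$T_b_C[w$strategy == "migrant"]) -
    mean(w$T_b_C[w$strategy == "resident"])
  dm_f <- mean(w$f_H_bpm[w$strategy == "migrant"]) -
    mean(w$f_H_bpm[w$strategy == "resident"])
  # 2 Monte-Carlo SEs: the individual intercept dominates (sd 0.15 degC and
  # 15 bpm, 30 birds per group -> SE about 0.039 degC and 3.9 bpm)
  expect_lt(abs(dm_t - 0.18), 2 * sqrt(2) * 0.15 / sqrt(30))
  expect_lt(abs(dm_f), 2 * sqrt(2) * 15 / sqrt(30))
})

test_that("QI corruption honours class probabilities and truth-sample cadence", {
  cfg <- sim_config(n_residents = 1, n_migrants = 0, seed = 5)
  pop <- generate_population(cfg)
  amb <- generate_ambient_series(cfg)
  clean <- generate_biologger_series(pop$metadata, pop$truth, amb, cfg)
  qi <- list(probs = c(0, 1, 0.2, 0), class_weights = c(0.3, 0.3, 0.3, 0.1),
             kernel = c(0.5, 2), truth_every = 120)
  rec <- corrupt_with_qi(clean, qi, seed = 11)
  changed <- rec$f_H_bpm != clean$f_H_bpm[match(rec$timestamp, clean$timestamp)]
  expect_true(all(!changed[rec$qi_class == 1]))
  expect_true(all(changed[rec$qi_class == 2]))
  r3 <- mean(changed[rec$qi_class == 3])   # binomial: 0.2 +- ~2 sd
  expect_lt(abs(r3 - 0.2), 0.02 * sqrt(5000 / sum(rec$qi_class == 3)) * 2)
  # T_b is never corrupted
  expect_identical(rec$T_b_C, clean$T_b_C[match(rec$timestamp, clean$timestamp)])
  # truth subsample exactly every 120th record per logger
  idx <- which(rec$has_ecg_truth)
  expect_equal(idx, seq(1, nrow(rec), by = 120))
  expect_true(all(!is.na(rec$true_fH_bpm[idx])))
  # invalid probabilities rejected
  expect_error(corrupt_with_qi(clean, list(probs = c(-0.1, 1), kernel = c(2),
                                           class_weights = c(0.5, 0.5),
                                           truth_every = 120)),
               "probabilities")
  # determinism
  rec2 <- corrupt_with_qi(clean, qi, seed = 11)
  expect_identical(rec, rec2)
})
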