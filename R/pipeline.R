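#' Run the whole analysis pipeline from one configuration
#'
#' Executes the stages in order — simulate, quality control, flight
#' classification and event derivation, staging/pairing comparisons,
#' scenario-gridded thermoregulation, and the energy-budget accounting — and
#' writes every stage artifact plus a run manifest to `out_dir`. With the
#' same configuration and seed the run is reproducible end to end.
#'
#' @param config a [sim_config()], or a path to a YAML file whose fields are
#'   passed to [sim_config()].
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @param stages character subset of c("simulate","qc","classify","stage",
#'   "thermo","budget"); later stages require the earlier ones.
#' @param train_frac fraction of migrants used for classifier training
#'   (bird-level split; the rest are held out).
#' @param n_trees boosting rounds for the classifier.
#' @param params_fn function(body_mass_kg) -> [thermo_params()] used for the
#'   thermoregulation stage.
#' @return invisible list with every stage result and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         stages = c("simulate", "qc", "classify", "stage",
                                    "thermo", "budget"),
                         train_frac = 0.5, n_trees = 300,
                         params_fn = function(m) thermo_params(body_mass_kg = m)) {
  if (is.character(config)) {
    config <- do.call(sim_config, yaml::read_yaml(config))
  }
  t0 <- Sys.time()
  out <- list(config = config)
  emit <- function(name, df) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      data.table::fwrite(df, file.path(out_dir, paste0(name, ".csv")))
    }
  }

  # simulate
  sim <- simulate_dataset(config)
  out$sim <- sim
  emit("metadata", sim$metadata)
  emit("events_truth", sim$truth$events)
  emit("records", format_records(sim$records))
  emit("ambient", sim$ambient)
  if (!"qc" %in% stages) return(invisible(finish(out, out_dir, t0)))

  qi_table <- estimate_qi_error_rates(sim$records)
  filt <- filter_by_quality(sim$records, qi_table)
  out$qi_table <- qi_table
  out$filtered <- filt
  emit("qi_error_table", qi_table)
  emit("exclusions", filt$report)
  if (!"classify" %in% stages) return(invisible(finish(out, out_dir, t0)))

  # classify: train on a bird-level split using ground-truth labels, apply
  # everywhere, derive events
  feats <- build_features(filt$records)
  set.seed(config$seed + 10L)
  birds <- unique(feats$bird_id)
  train_birds <- sample(birds, max(2, round(train_frac * length(birds))))
  tr <- feats[feats$bird_id %in% train_birds & feats$is_night, ]
  model <- train_migration_model(tr, tr$is_flight, n_trees = n_trees,
                                 seed = config$seed + 11L)
  classified <- classify_measurements(model, feats[feats$is_night, ])
  calls <- aggregate_nights(classified)
  events <- derive_migration_events(calls)
  out$model <- model
  out$classified <- classified
  out$night_calls <- calls
  out$events <- events
  out$evaluation <- evaluate_classifier(classified)
  emit("night_calls", calls)
  emit("events_inferred", events$events)
  if (!"stage" %in% stages) return(invisible(finish(out, out_dir, t0)))

  # staging, pairing, mixed-model comparison
  recs <- label_calendar_seasons(filt$records)
  recs$strategy <- sim$metadata$strategy[match(recs$bird_id, sim$metadata$bird_id)]
  recs$sex <- sim$metadata$sex[match(recs$bird_id, sim$metadata$bird_id)]
  mig <- label_migration_stages(recs[recs$strategy == "migrant", ], events)
  pairing <- pair_residents_to_migrants(mig, recs[recs$strategy == "resident", ],
                                        sim$metadata, seed = config$seed + 12L)
  thin <- thin_autocorrelation(recs[recs$season != "none", ],
                               seed = config$seed + 13L)
  lmm <- list(
    f_H = compare_groups_lmm(thin, "f_H_bpm"),
    T_b = compare_groups_lmm(thin, "T_b_C")
  )
  out$paired <- pairing
  out$lmm <- lmm
  emit("lmm_contrasts_fH", lmm$f_H$contrasts)
  emit("lmm_contrasts_Tb", lmm$T_b$contrasts)
  if (!"thermo" %in% stages) return(invisible(finish(out, out_dir, t0)))

  scenarios <- build_scenarios(sim$ambient, events)
  ledgers <- lapply(scenarios, function(sc) {
    population_thermo_ledgers(filt$tb_records, sim$metadata, events, sc,
                              params_fn = params_fn)
  })
  out$scenarios <- scenarios
  out$ledgers <- ledgers
  if (!"budget" %in% stages) return(invisible(finish(out, out_dir, t0)))

  win <- absence_window(events)
  savings_grid <- do.call(rbind, lapply(names(ledgers), function(nm) {
    s <- strategy_savings(ledgers[[nm]], sim$metadata, window = win)
    data.frame(scenario = nm, delta_kJ = s$delta_kJ, fold = s$fold,
               resident_kJ = s$resident_kJ, migrant_kJ = s$migrant_kJ)
  }))
  mig_ids <- sim$metadata$bird_id[sim$metadata$strategy == "migrant"]
  fi <- estimate_flight_intervals(classified, filt$tb_records)
  flight_kJ <- vapply(mig_ids, function(b) {
    n_int <- fi$n_intervals[fi$bird_id == b]
    if (length(n_int) == 0) n_int <- 0
    flight_energy(sim$metadata$body_mass_kg[sim$metadata$bird_id == b], n_int)
  }, numeric(1))
  frac <- flight_fraction(flight_kJ, savings_grid,
                          central_scenario = "off0_mean")
  trend <- fit_thermo_trend(ledgers[["off0_mean"]], sim$metadata)
  out$savings_grid <- savings_grid
  out$flight_kJ <- flight_kJ
  out$flight_fraction <- frac
  out$trend <- trend
  emit("savings_grid", savings_grid)
  emit("thermo_trend", trend$smooths)
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(savings = savings_grid,
           flight_kJ = as.list(flight_kJ),
           flight_fraction = frac[c("central_pct", "min_pct", "max_pct")]),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(finish(out, out_dir, t0))
}

format_records <- function(records) {
  r <- records
  r$timestamp <- format(r$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  r
}

finish <- function(out, out_dir, t0) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("migenergy")),
    r_version = R.version.string,
    seed = out$config$seed,
    config_hash = config_hash(out$config),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  out$manifest <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  out
}

# stable hash of the configuration via its serialized YAML text
config_hash <- function(config) {
  txt <- yaml::as.yaml(lapply(config, function(x)
    if (inherits(x, "Date")) as.character(x) else x))
  f <- tempfile()
  writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}
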