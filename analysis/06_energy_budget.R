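#!/usr/bin/env Rscript
# Stage 6: the energy accounting - thermoregulatory savings of migrating to a
# warmer wintering area versus the allometric cost of the migratory flights.
#
# Runs the full pipeline (simulate -> qc -> classify -> thermo -> budget) on
# the budget-recovery configuration and compares the pipeline estimates with
# the generator's ground truth.

library(migenergy)

cfg <- budget_recovery_config(seed = 1)
res <- suppressWarnings(run_pipeline(cfg, out_dir = "results/06_budget",
                                     params_fn = budget_recovery_params))

cat("savings grid (resident - migrant thermoregulatory energy):\n")
print(res$savings_grid[, c("scenario", "delta_kJ", "fold")], digits = 4)
cat(sprintf("\nmean migrant flight energy: %.0f kJ\n", mean(res$flight_kJ)))
cat(sprintf("flight cost as %% of savings: %.1f%% (range %.1f-%.1f%% over the grid)\n",
            res$flight_fraction$central_pct, res$flight_fraction$min_pct,
            res$flight_fraction$max_pct))

# ground truth from the generator's latent state
sim <- res$sim
sc <- build_scenarios(sim$ambient, sim$truth)
led <- population_thermo_ledgers(sim$clean, sim$metadata, sim$truth,
                                 sc$off0_mean, params_fn = budget_recovery_params)
sv <- strategy_savings(led, sim$metadata, window = absence_window(sim$truth))
mig_ids <- sim$metadata$bird_id[sim$metadata$strategy == "migrant"]
true_flight <- sapply(mig_ids, function(b)
  flight_energy(sim$metadata$body_mass_kg[sim$metadata$bird_id == b],
                sum(sim$clean$is_flight[sim$clean$bird_id == b])))
cat(sprintf("\nground truth: savings %.0f kJ, fold %.3f, flight %.0f kJ, ratio %.2f%%\n",
            sv$delta_kJ, sv$fold, mean(true_flight),
            100 * mean(true_flight) / sv$delta_kJ))
cat(sprintf("pipeline:     savings %.0f kJ, fold %.3f, ratio %.2f%%\n",
            res$savings_grid$delta_kJ[res$savings_grid$scenario == "off0_mean"],
            res$savings_grid$fold[res$savings_grid$scenario == "off0_mean"],
            res$flight_fraction$central_pct))
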