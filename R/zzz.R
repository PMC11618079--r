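# silence R CMD check notes for data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".N", ".SD", "wrong", "n_truth_samples", "error_rate", "scale_cut",
  "f_H_bpm", "T_b_C", "fH_mu", "fH_sd", "Tb_mu", "Tb_sd", "fH_scaled",
  "Tb_scaled", "fH_diff_mean", "Tb_diff_mean", "Tb_prev", "Tb_prop_increase",
  "logger_int", "logger_id", "timestamp", "bird_id", "lab", "call",
  "flight_fraction", "sex", "slot", "n_mig", "idx", "grp_start",
  "rank_in_slot", "day", "kJ", "strategy", "jday", "N", "n_intervals"
))
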