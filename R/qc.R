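#' Calibrate per-logger, per-QI heart-rate error rates from ECG truth samples
#'
#' The logger's internal quality index (QI) is based on each logger's own
#' signal history, so it is not comparable across loggers: error rates must
#' be calibrated per logger. For every record carrying a raw-ECG truth value,
#' the logger-computed f_H is scored wrong when its relative deviation from
#' the truth exceeds `mismatch_tolerance`; the error rate of a (logger, QI)
#' cell is the fraction of wrong truth samples. Cells with fewer than
#' `min_truth_samples` truth records get an undefined (NA) rate, never zero.
#'
#' @param records data.frame with logger_id, qi_class, f_H_bpm,
#'   has_ecg_truth, true_fH_bpm.
#' @param mismatch_tolerance relative deviation above which a logger value
#'   counts as wrong (default 0.10).
#' @param min_truth_samples minimum truth samples to define a rate.
#' @return data.frame: logger_id, qi_class, n_truth_samples, error_rate.
#' @export
estimate_qi_error_rates <- function(records, mismatch_tolerance = 0.10,
                                    min_truth_samples = 5) {
  stopifnot(mismatch_tolerance >= 0)
  if (!any(records$has_ecg_truth)) {
    stop("records contain no ECG truth subsamples; cannot calibrate error rates")
  }
  dt <- data.table::as.data.table(records)
  tr <- dt[dt$has_ecg_truth & !is.na(dt$true_fH_bpm)]
  tr[, wrong := abs(f_H_bpm - true_fH_bpm) / true_fH_bpm > mismatch_tolerance]
  tab <- tr[, list(n_truth_samples = .N, error_rate = mean(wrong)),
            by = c("logger_id", "qi_class")]
  # cells present in the data but unseen in the truth subsample
  cells <- unique(dt[, c("logger_id", "qi_class"), with = FALSE])
  tab <- merge(cells, tab, by = c("logger_id", "qi_class"), all.x = TRUE)
  tab[is.na(n_truth_samples), n_truth_samples := 0L]
  tab[n_truth_samples < min_truth_samples, error_rate := NA_real_]
  data.table::setorderv(tab, c("logger_id", "qi_class"))
  as.data.frame(tab)
}

#' Filter measurements by calibrated QI error rate and plausibility bounds
#'
#' Keeps heart-rate measurements whose (logger, QI) error rate is known and
#' below `max_error` and whose value lies inside the plausible f_H range.
#' Body-temperature measurements are trusted independently of the f_H filter
#' (the T_b sensor is factory-calibrated), so the full record set is returned
#' separately for T_b analyses. Loggers with no passing QI class are listed
#' in the exclusion report.
#'
#' @param records records data.frame (with qi_class).
#' @param table calibration table from [estimate_qi_error_rates()].
#' @param max_error maximum acceptable QI error rate (default 0.15).
#' @param fh_bounds plausible f_H range in bpm (default c(60, 800); the
#'   field-verified range is dataset-specific and config-exposed).
#' @return list: `records` (f_H-clean subset), `tb_records` (all input
#'   records, for T_b analyses), `excluded_loggers` (character vector),
#'   `report` (per-logger kept/dropped counts).
#' @export
filter_by_quality <- function(records, table, max_error = 0.15,
                              fh_bounds = c(60, 800)) {
  if (nrow(records) == 0) {
    return(list(records = records, tb_records = records,
                excluded_loggers = character(0),
                report = data.frame(logger_id = character(0),
                                    kept = integer(0), dropped = integer(0))))
  }
  missing <- setdiff(unique(records$logger_id), unique(table$logger_id))
  if (length(missing)) {
    stop("calibration table does not cover loggers: ",
         paste(missing, collapse = ", "))
  }
  key_rec <- paste(records$logger_id, records$qi_class)
  key_tab <- paste(table$logger_id, table$qi_class)
  rate <- table$error_rate[match(key_rec, key_tab)]
  pass_qi <- !is.na(rate) & rate < max_error
  in_bounds <- records$f_H_bpm >= fh_bounds[1] & records$f_H_bpm <= fh_bounds[2]
  keep <- pass_qi & in_bounds
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  counts <- table(factor(records$logger_id), keep)
  report <- data.frame(
    logger_id = rownames(counts),
    kept = as.integer(if ("TRUE" %in% colnames(counts)) counts[, "TRUE"] else 0L),
    dropped = as.integer(if ("FALSE" %in% colnames(counts)) counts[, "FALSE"] else 0L),
    stringsAsFactors = FALSE
  )
  excluded <- report$logger_id[report$kept == 0L]
  list(records = kept, tb_records = records, excluded_loggers = excluded,
       report = report)
}
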