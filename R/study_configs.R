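#' Study configuration for end-to-end budget recovery
#'
#' A generator configuration plus thermoregulation parameterisation whose
#' ground-truth flight-energy-to-thermoregulatory-savings ratio sits near 7%
#' of the savings — the regime the full pipeline is expected to recover. The
#' biophysical side emulates an exposed, windy winter microsite with lean
#' plumage insulation (whole-animal thermal conductance near 0.19 W/K, the
#' high-conductance regime in which mechanistic endotherm models operate once
#' wind is accounted for); migration departures are concentrated within a
#' ten-day window per season and flight bouts last 2.5-4.5 h per migration
#' night.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
budget_recovery_config <- function(seed = 1) {
  sim_config(
    n_residents = 10, n_migrants = 8,
    flight = list(delta_fh = 199, delta_tb = 1.23,
                  bout_hours_min = 2.5, bout_hours_max = 4.5),
    phenology = list(fall_window = c("2021-10-05", "2021-10-15"),
                     spring_window = c("2022-03-10", "2022-03-20"),
                     nights_min = 1, nights_mean = 4, nights_max = 9,
                     stopover_mean = 2),
    seed = seed
  )
}

#' @rdname budget_recovery_config
#' @param body_mass_kg body mass of the bird being parameterised.
#' @export
budget_recovery_params <- function(body_mass_kg) {
  thermo_params(body_mass_kg = body_mass_kg,
                plumage_depth_m = 0.0025,
                plumage_conductivity_W_mK = 0.065,
                wind_speed_m_s = 8)
}
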