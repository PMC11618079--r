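STEFAN_BOLTZMANN <- 5.670e-8  # W m-2 K-4

#' Biophysical parameters for the one-node endotherm heat-balance model
#'
#' A homeotherm is modelled as a prolate ellipsoid of flesh wrapped in a
#' plumage layer, exchanging heat with the environment by conduction through
#' flesh and plumage in series with convection and thermal radiation from the
#' outer surface. Defaults describe a blackbird-sized (90 g) passerine in its
#' cold-season plumage; every value is a configuration input.
#'
#' @param body_mass_kg body mass (kg).
#' @param body_density_kg_m3 tissue density (kg m-3).
#' @param elongation prolate ellipsoid long-to-short axis ratio.
#' @param plumage_depth_m plumage layer thickness (m).
#' @param plumage_conductivity_W_mK effective plumage thermal conductivity
#'   (W m-1 K-1); feather-air composite, close to still air.
#' @param flesh_thickness_m conductive flesh shell thickness (m).
#' @param flesh_conductivity_W_mK flesh thermal conductivity (W m-1 K-1).
#' @param wind_speed_m_s wind speed (m s-1).
#' @param air_conductivity_W_mK thermal conductivity of air (W m-1 K-1).
#' @param air_kinematic_viscosity_m2_s kinematic viscosity of air (m2 s-1).
#' @param emissivity surface longwave emissivity, in (0, 1].
#' @param basal_power_W basal metabolic power (W); default from the passerine
#'   allometry [basal_power_passerine()] at the configured mass.
#' @return list of class `thermo_params`.
#' @export
thermo_params <- function(body_mass_kg = 0.090,
                          body_density_kg_m3 = 1000,
                          elongation = 2.0,
                          plumage_depth_m = 0.010,
                          plumage_conductivity_W_mK = 0.040,
                          flesh_thickness_m = 0.005,
                          flesh_conductivity_W_mK = 0.5,
                          wind_speed_m_s = 1.0,
                          air_conductivity_W_mK = 0.0243,
                          air_kinematic_viscosity_m2_s = 1.32e-5,
                          emissivity = 0.95,
                          basal_power_W = basal_power_passerine(body_mass_kg)) {
  p <- list(body_mass_kg = body_mass_kg,
            body_density_kg_m3 = body_density_kg_m3,
            elongation = elongation,
            plumage_depth_m = plumage_depth_m,
            plumage_conductivity_W_mK = plumage_conductivity_W_mK,
            flesh_thickness_m = flesh_thickness_m,
            flesh_conductivity_W_mK = flesh_conductivity_W_mK,
            wind_speed_m_s = wind_speed_m_s,
            air_conductivity_W_mK = air_conductivity_W_mK,
            air_kinematic_viscosity_m2_s = air_kinematic_viscosity_m2_s,
            emissivity = emissivity,
            basal_power_W = basal_power_W)
  stopifnot(all(unlist(p[setdiff(names(p), "wind_speed_m_s")]) > 0),
            p$wind_speed_m_s >= 0, p$emissivity <= 1)
  class(p) <- "thermo_params"
  p
}

#' Passerine basal metabolic power
#'
#' Classic passerine allometry (Lasiewski-Dawson): BMR in kcal/day equals
#' 129 M^0.724 with M in kg, converted to watts. About 1.09 W for a 90 g
#' bird.
#'
#' @param mass_kg body mass (kg).
#' @return watts.
#' @export
basal_power_passerine <- function(mass_kg) {
  129 * mass_kg^0.724 * 4.184 / 86.4
}

#' Body geometry from mass
#'
#' Prolate ellipsoid of the given mass and density: semi-axes from volume and
#' elongation, skin surface area via the standard approximation (exponent
#' 1.6075), outer surface at semi-axes enlarged by the plumage depth, and the
#' characteristic dimension (diameter of the sphere of equal outer volume)
#' for the convection correlations.
#'
#' @param mass_kg,density_kg_m3,elongation body mass, density, axis ratio.
#' @param plumage_depth_m plumage thickness added to all semi-axes.
#' @return list: volume_m3, semi_axes (a, b, c), area_skin_m2, area_outer_m2,
#'   char_dim_m.
#' @export
geometry_from_mass <- function(mass_kg, density_kg_m3 = 1000, elongation = 2.0,
                               plumage_depth_m = 0.010) {
  stopifnot(mass_kg > 0, density_kg_m3 > 0, elongation > 0, plumage_depth_m >= 0)
  volume <- mass_kg / density_kg_m3
  b <- (3 * volume / (4 * pi * elongation))^(1 / 3)
  a <- elongation * b
  area_skin <- ellipsoid_area(a, b, b)
  area_outer <- ellipsoid_area(a + plumage_depth_m, b + plumage_depth_m,
                               b + plumage_depth_m)
  vol_outer <- 4 / 3 * pi * (a + plumage_depth_m) * (b + plumage_depth_m)^2
  list(volume_m3 = volume, semi_axes = c(a = a, b = b, c = b),
       area_skin_m2 = area_skin, area_outer_m2 = area_outer,
       char_dim_m = 2 * (3 * vol_outer / (4 * pi))^(1 / 3))
}

# Thomsen approximation for the ellipsoid surface, exponent p = 1.6075
ellipsoid_area <- function(a, b, c, p = 1.6075) {
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

#' Convective and radiative surface heat-transfer coefficients
#'
#' Forced convection from the Nusselt-Reynolds correlation Nu = 0.37 Re^0.6
#' with a free-convection floor of Nu = 2, and the linearized radiative
#' coefficient h_rad = 4 epsilon sigma T_film^3 evaluated at the film
#' temperature.
#'
#' @param geometry output of [geometry_from_mass()].
#' @param params a [thermo_params()].
#' @param T_film_C film temperature (degC).
#' @return list(h_conv, h_rad) in W m-2 K-1.
#' @export
heat_transfer_coefficients <- function(geometry, params, T_film_C) {
  D <- geometry$char_dim_m
  Re <- params$wind_speed_m_s * D / params$air_kinematic_viscosity_m2_s
  Nu <- pmax(2, 0.37 * Re^0.6)
  list(h_conv = Nu * params$air_conductivity_W_mK / D,
       h_rad = 4 * params$emissivity * STEFAN_BOLTZMANN * (T_film_C + 273.15)^3)
}

#' Heat loss required to hold body temperature against ambient temperature
#'
#' Series thermal network: conduction through the flesh shell, conduction
#' through the plumage (at the mean of inner and outer areas), and a combined
#' convective-radiative boundary layer at the outer surface, with the film
#' temperature fixed at the midpoint of T_b and T_a (no surface-temperature
#' iteration). Q_req = (T_b - T_a) / R_total; a warmer environment than the
#' body returns 0 (no heating load is modelled).
#'
#' @param T_b,T_a body and ambient temperature (degC); vectorized.
#' @param params a [thermo_params()].
#' @return watts.
#' @export
required_heat_loss <- function(T_b, T_a, params) {
  if (any(!is.finite(T_b)) || any(!is.finite(T_a))) {
    stop("non-finite temperatures in heat-balance input")
  }
  g <- geometry_from_mass(params$body_mass_kg, params$body_density_kg_m3,
                          params$elongation, params$plumage_depth_m)
  h <- heat_transfer_coefficients(g, params, (T_b + T_a) / 2)
  A_mean <- (g$area_skin_m2 + g$area_outer_m2) / 2
  R <- params$flesh_thickness_m / (params$flesh_conductivity_W_mK * g$area_skin_m2) +
    params$plumage_depth_m / (params$plumage_conductivity_W_mK * A_mean) +
    1 / ((h$h_conv + h$h_rad) * g$area_outer_m2)
  pmax(0, (T_b - T_a) / R)
}

#' Total and above-basal thermoregulatory power
#'
#' Metabolic heat production must at least cover the required heat loss;
#' below the thermoneutral load the animal idles at basal power. total =
#' max(basal, Q_req); above_basal = max(0, Q_req - basal).
#'
#' @inheritParams required_heat_loss
#' @return data.frame(total_W, above_basal_W) (with Q_req_W).
#' @export
thermo_power <- function(T_b, T_a, params) {
  q <- required_heat_loss(T_b, T_a, params)
  data.frame(Q_req_W = q,
             total_W = pmax(params$basal_power_W, q),
             above_basal_W = pmax(0, q - params$basal_power_W))
}

#' Simulate the thermoregulatory ledger for one bird and scenario
#'
#' Joins the observed body-temperature series with the experienced ambient
#' series on the shared 30-min grid, evaluates the heat balance per interval,
#' and accumulates energy (power x 1800 s per interval, reported in kJ).
#' Ambient gaps are forward-filled up to `max_fill` consecutive intervals,
#' then the run aborts naming the offending timestamps.
#'
#' @param tb_series data.frame timestamp, T_b_C for one bird.
#' @param ta_series data.frame timestamp, T_a_C (same grid or a superset).
#' @param params a [thermo_params()].
#' @param bird_id,scenario labels copied into the ledger.
#' @param max_fill maximum consecutive ambient intervals to forward-fill.
#' @return ledger data.frame: bird_id, scenario, timestamp, T_b_C, T_a_C,
#'   Q_req_W, total_W, above_basal_W, cum_kJ (cumulative on total power).
#' @export
simulate_thermo_series <- function(tb_series, ta_series, params,
                                   bird_id = "bird", scenario = "baseline",
                                   max_fill = 4) {
  ta <- ta_series$T_a_C[match(as.numeric(tb_series$timestamp),
                              as.numeric(ta_series$timestamp))]
  if (anyNA(ta)) {
    gap <- is.na(ta)
    r <- rle(gap)
    if (max(r$lengths[r$values]) > max_fill) {
      bad <- tb_series$timestamp[gap]
      stop("ambient series does not cover timestamps (gap > ", max_fill,
           " intervals), e.g. ", format(bad[1], tz = "UTC"))
    }
    idx <- which(!gap)
    ta <- ta[idx][findInterval(seq_along(ta), idx)]  # forward fill
  }
  pw <- thermo_power(tb_series$T_b_C, ta, params)
  dt_s <- 1800
  ledger <- data.frame(bird_id = bird_id, scenario = scenario,
                       timestamp = tb_series$timestamp,
                       T_b_C = tb_series$T_b_C, T_a_C = ta,
                       Q_req_W = pw$Q_req_W, total_W = pw$total_W,
                       above_basal_W = pw$above_basal_W)
  ledger$cum_kJ <- cumsum(ledger$total_W * dt_s / 1000)
  ledger
}

#' Thermoregulatory ledgers for a whole population under one scenario
#'
#' Runs [simulate_thermo_series()] for every bird: residents on the scenario
#' resident series, migrants on their individually experienced series
#' (converging from breeding to wintering temperatures over their migration
#' nights).
#'
#' @param records clean or filtered records providing per-bird T_b series.
#' @param metadata bird metadata (strategy, body mass).
#' @param events `migration_events` or `migration_truth` for the migrants.
#' @param scenario one element of [build_scenarios()].
#' @param params_fn function(body_mass_kg) -> [thermo_params()]; default
#'   builds the blackbird parameterisation at each bird's mass.
#' @return combined ledger data.frame.
#' @export
population_thermo_ledgers <- function(records, metadata, events, scenario,
                                      params_fn = function(m) thermo_params(body_mass_kg = m)) {
  res30 <- to_halfhour(scenario$resident)
  win30 <- to_halfhour(scenario$wintering)
  out <- list()
  for (i in seq_len(nrow(metadata))) {
    md <- metadata[i, ]
    tb <- records[records$bird_id == md$bird_id, c("timestamp", "T_b_C")]
    if (nrow(tb) == 0) next
    if (md$strategy == "resident") {
      ta <- res30
    } else {
      ev <- events$events[events$events$bird_id == md$bird_id, ]
      nt <- events$nights[events$nights$bird_id == md$bird_id, ]
      if ("type" %in% names(nt)) nt <- nt[nt$type == "flight", ]
      bre30 <- if (!is.null(scenario$breeding)) to_halfhour(scenario$breeding) else res30
      ta <- experienced_temperature(ev, nt, bre30, win30)
    }
    out[[md$bird_id]] <- simulate_thermo_series(
      tb, ta, params_fn(md$body_mass_kg),
      bird_id = md$bird_id, scenario = scenario$label
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
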