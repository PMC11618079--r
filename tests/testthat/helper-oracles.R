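# Independent oracles used across the suite. These re-derive quantities by a
# different route than the package implementation.

# Solve the one-node heat balance by bisection on the outer-surface
# temperature: conduction from the body core through flesh and plumage must
# equal convective + radiative loss from the outer surface. Same physics,
# different solution path than the closed-form series-resistance formula.
bisection_heat_loss <- function(T_b, T_a, params, tol = 1e-12) {
  g <- geometry_from_mass(params$body_mass_kg, params$body_density_kg_m3,
                          params$elongation, params$plumage_depth_m)
  h <- heat_transfer_coefficients(g, params, (T_b + T_a) / 2)
  A_mean <- (g$area_skin_m2 + g$area_outer_m2) / 2
  R_int <- params$flesh_thickness_m /
    (params$flesh_conductivity_W_mK * g$area_skin_m2) +
    params$plumage_depth_m / (params$plumage_conductivity_W_mK * A_mean)
  h_out <- (h$h_conv + h$h_rad) * g$area_outer_m2
  if (T_b <= T_a) return(0)
  f <- function(T_o) (T_b - T_o) / R_int - h_out * (T_o - T_a)
  lo <- T_a; hi <- T_b
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  h_out * ((lo + hi) / 2 - T_a)
}

# Prolate spheroid surface area by numerical quadrature of the surface of
# revolution: S = 2*pi * int_{-a}^{a} y(x) sqrt(1 + y'(x)^2) dx with
# y(x) = b sqrt(1 - x^2/a^2).
spheroid_area_quadrature <- function(a, b) {
  integrand <- function(x) {
    y <- b * sqrt(pmax(0, 1 - x^2 / a^2))
    dy <- ifelse(abs(x) < a, -b * x / (a^2 * sqrt(pmax(1e-300, 1 - x^2 / a^2))), 0)
    y * sqrt(1 + dy^2)
  }
  2 * pi * stats::integrate(integrand, -a, a, rel.tol = 1e-10,
                            subdivisions = 2000L)$value
}

# toy record builder for QC tests
toy_records <- function(n, logger = "L1", qi = 1L, fh = 400, tb = 40,
                        truth_every = NA, start = "2021-09-01") {
  ts <- halfhour_grid(start, as.Date(start) + ceiling(n / 48), 30)[seq_len(n)]
  r <- data.frame(
    bird_id = logger, logger_id = logger, timestamp = ts,
    f_H_bpm = rep_len(fh, n), T_b_C = rep_len(tb, n),
    is_night = is_night_time(ts), is_flight = FALSE,
    qi_class = rep_len(qi, n), stringsAsFactors = FALSE
  )
  if (!is.na(truth_every)) {
    idx <- seq(1, n, by = truth_every)
    r$has_ecg_truth <- seq_len(n) %in% idx
    r$true_fH_bpm <- ifelse(r$has_ecg_truth, r$f_H_bpm, NA_real_)
  } else {
    r$has_ecg_truth <- FALSE
    r$true_fH_bpm <- NA_real_
  }
  r
}

# constant-temperature ambient series on the 30-min grid
constant_series <- function(value, start = "2021-09-01", end = "2022-04-10") {
  g <- halfhour_grid(start, end)
  data.frame(timestamp = g, T_a_C = rep(value, length(g)))
}
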