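#' Half-hour measurement grid
#'
#' Regular POSIXct grid (UTC) covering `start` .. `end` at the logger cadence.
#'
#' @param start,end Dates (or strings) giving the first and last day, inclusive.
#' @param cadence_min cadence in minutes; must divide 24 h.
#' @return POSIXct vector.
#' @export
halfhour_grid <- function(start, end, cadence_min = 30) {
  stopifnot((24 * 60) %% cadence_min == 0)
  seq(
    as.POSIXct(paste(as.Date(start), "00:00:00"), tz = "UTC"),
    as.POSIXct(paste(as.Date(end), "23:59:59"), tz = "UTC"),
    by = cadence_min * 60
  )
}

#' Approximate daylength from the sunrise equation
#'
#' Daylength (hours) at a given latitude and day of year, from the standard
#' solar-declination sinusoid. Used to split measurements into day and night
#' without an ephemeris dependency.
#'
#' @param doy day of year (1-366).
#' @param latitude degrees north.
#' @return hours of daylight.
#' @export
daylength_hours <- function(doy, latitude) {
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365.25) * pi / 180
  phi <- latitude * pi / 180
  x <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  2 * acos(x) * 12 / pi
}

#' Night flag for timestamps
#'
#' A timestamp is nocturnal when its UTC hour falls outside the daylight
#' window centred on 12:00 (solar noon approximation).
#'
#' @param timestamp POSIXct.
#' @param latitude degrees north.
#' @return logical vector.
#' @export
is_night_time <- function(timestamp, latitude = 47.7) {
  doy <- as.POSIXlt(timestamp, tz = "UTC")$yday + 1
  hr <- as.POSIXlt(timestamp, tz = "UTC")$hour +
    as.POSIXlt(timestamp, tz = "UTC")$min / 60
  half <- daylength_hours(doy, latitude) / 2
  abs(hr - 12) > half
}

#' Date at dusk indexing a night
#'
#' Nights span midnight; all nocturnal measurements of one night are indexed
#' by the calendar date at dusk (timestamps up to noon the following day map
#' back to the previous date).
#'
#' @param timestamp POSIXct.
#' @return Date vector.
#' @export
night_date <- function(timestamp) {
  as.Date(timestamp - 12 * 3600, tz = "UTC")
}

# stationary AR(1) noise with marginal standard deviation sd
ar1_noise <- function(n, phi, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i - 1]
  }
  x
}

#' Relative tag burden
#'
#' Combined mass of an implanted logger and an external transmitter as a
#' percentage of body mass.
#'
#' @param implant_g implant mass (g), default the 3.3 g heart-rate/temperature
#'   logger.
#' @param transmitter_g transmitter mass (g); the heaviest deployed backpack
#'   is 2.6 g.
#' @param body_mass_g body mass (g); 90 g is the mean for a blackbird.
#' @return percent of body mass.
#' @export
tag_burden <- function(implant_g = 3.3, transmitter_g = 2.6, body_mass_g = 90) {
  stopifnot(body_mass_g > 0)
  100 * (implant_g + transmitter_g) / body_mass_g
}

# maximal runs of x where two confidence bands do not overlap.
# bands: data.frame with columns x, lo1, hi1, lo2, hi2 (sorted by x).
# Returns data.frame(start, end, sign) where sign is +1 when band 1 sits
# above band 2 over the run.
ci_nonoverlap_windows <- function(bands) {
  sep <- ifelse(bands$lo1 > bands$hi2, 1L, ifelse(bands$lo2 > bands$hi1, -1L, 0L))
  out <- data.frame(start = numeric(0), end = numeric(0), sign = integer(0))
  r <- rle(sep)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] != 0L) {
      out <- rbind(out, data.frame(
        start = bands$x[idx_start[k]],
        end = bands$x[idx_end[k]],
        sign = r$values[k]
      ))
    }
  }
  out
}
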