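#' Interpolate an hourly temperature series to the 30-min logger grid
#'
#' Physiological measurements arrive every half hour but weather series are
#' hourly; midpoints are filled by linear interpolation (each new point is
#' the mean of its neighbours), endpoints are preserved.
#'
#' @param series data.frame with timestamp (strictly increasing) and T_a_C;
#'   a site column, if present, must be constant.
#' @return data.frame on the 30-min grid.
#' @export
to_halfhour <- function(series) {
  ts <- series$timestamp
  if (anyDuplicated(ts)) stop("duplicate timestamps in ambient series")
  if (is.unsorted(as.numeric(ts))) stop("ambient timestamps must be increasing")
  grid <- seq(ts[1], ts[length(ts)], by = 1800)
  out <- data.frame(
    timestamp = grid,
    T_a_C = stats::approx(as.numeric(ts), series$T_a_C, xout = as.numeric(grid))$y
  )
  if ("site" %in% names(series)) out <- cbind(site = series$site[1], out)
  out
}

#' Ambient temperature experienced by one bird
#'
#' Residents experience the breeding-site series throughout. For a migrant
#' with n fall flight nights, the journey is split into n segments: after the
#' k-th flight night the experienced temperature is the convex combination
#' (1 - k/n) * breeding + (k/n) * wintering, converging linearly to the
#' wintering series night by night; spring reverses the weights symmetrically
#' back to the breeding site. Weights update at the end of each flight night
#' (from the following day).
#'
#' @param bird_events one-row data.frame of events for the bird (or NULL /
#'   all-NA for a resident).
#' @param flight_nights data.frame of the bird's flight nights (night_date,
#'   season), required for migrants.
#' @param breeding,wintering temperature series (timestamp, T_a_C) on a
#'   shared grid covering the season.
#' @return data.frame timestamp, T_a_C, weight.
#' @export
experienced_temperature <- function(bird_events, flight_nights,
                                    breeding, wintering) {
  stopifnot(nrow(breeding) == nrow(wintering),
            all(breeding$timestamp == wintering$timestamp))
  ts <- breeding$timestamp
  if (is.null(bird_events) || nrow(bird_events) == 0 ||
      is.na(bird_events$fall_departure)) {
    return(data.frame(timestamp = ts, T_a_C = breeding$T_a_C, weight = 0))
  }
  fall <- sort(flight_nights$night_date[flight_nights$season == "fall"])
  spring <- sort(flight_nights$night_date[flight_nights$season == "spring"])
  if (length(fall) == 0) stop("migrant with zero fall flight nights")
  date <- as.Date(ts, tz = "UTC")
  progress <- function(nights) {
    # fraction of the journey's flight nights completed by each date
    # (a night counts once the date is past it: weights update at night end)
    done <- rowSums(outer(date, nights, ">"))
    done / length(nights)
  }
  w <- progress(fall)
  if (length(spring)) {
    back <- progress(spring)
    w <- ifelse(date <= min(spring), w, 1 - back)
  }
  data.frame(timestamp = ts, T_a_C = (1 - w) * breeding$T_a_C + w * wintering$T_a_C,
             weight = w)
}

#' Build the resident-offset by wintering-quantile scenario grid
#'
#' Crosses resident micro-climate offsets (added to the breeding series only
#' while migrants are off-site, to bracket micro-climatic buffering) with the
#' wintering-site temperature series choices (mean and its 25th/75th
#' quantiles). The default 3 x 3 grid has 9 scenarios.
#'
#' @param ambient ambient series from [generate_ambient_series()] (or any
#'   data.frame with sites breeding, wintering_mean, wintering_q25,
#'   wintering_q75), on a shared grid.
#' @param events migration events (for the migrant-absence window).
#' @param resident_offsets degC added to resident temperatures inside the
#'   absence window (default c(0, 1, 2)).
#' @param wintering_quantiles which wintering series to use (default mean,
#'   q25, q75).
#' @return list of scenarios; each has label, resident_offset,
#'   wintering_quantile, resident (series) and wintering (series).
#' @export
build_scenarios <- function(ambient, events,
                            resident_offsets = c(0, 1, 2),
                            wintering_quantiles = c("mean", "q25", "q75")) {
  breeding <- ambient[ambient$site == "breeding", c("timestamp", "T_a_C")]
  win <- absence_window(events)
  scenarios <- list()
  for (off in resident_offsets) {
    res <- breeding
    if (!is.null(win) && off != 0) {
      d <- as.Date(res$timestamp, tz = "UTC")
      inside <- d >= win[1] & d <= win[2]
      res$T_a_C[inside] <- res$T_a_C[inside] + off
    }
    for (q in wintering_quantiles) {
      wsite <- paste0("wintering_", q)
      wint <- ambient[ambient$site == wsite, c("timestamp", "T_a_C")]
      if (nrow(wint) == 0) stop("ambient series missing site ", wsite)
      scenarios[[paste0("off", off, "_", q)]] <- list(
        label = paste0("offset+", off, "/", q),
        resident_offset = off, wintering_quantile = q,
        resident = res, wintering = wint, breeding = breeding
      )
    }
  }
  scenarios
}
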