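#' Accumulate degree-days from daily mean temperatures
#'
#' Thermal time above a base temperature, accumulated from the first date
#' (bloom, dd = 0 origin taken before the first day's increment is added).
#' The series must be gap-free: a missing calendar day is an error, never
#' silently interpolated.
#'
#' @param dates Date vector (one per day, consecutive).
#' @param tmean daily mean air temperature, degC.
#' @param base base temperature, degC (>= 0). Default 7, standard for peach.
#' @return numeric vector of cumulative degree-days, same length as input.
#' @examples
#' accumulate_degree_days(as.Date("2011-04-01") + 0:9, rep(17, 10), base = 7)
#' @export
accumulate_degree_days <- function(dates, tmean, base = 7) {
  stopifnot(length(dates) == length(tmean), base >= 0)
  if (any(!is.finite(tmean))) stop("non-finite daily mean temperature")
  dates <- as.Date(dates)
  if (length(dates) > 1) {
    gaps <- diff(as.integer(dates))
    if (any(gaps != 1L)) {
      bad <- which(gaps != 1L)[1]
      stop(sprintf("gap in daily series between %s and %s",
                   dates[bad], dates[bad + 1]))
    }
  }
  cumsum(pmax(0, tmean - base))
}

#' Hourly collar water potential from predawn and midday values
#'
#' Reconstructs the diurnal course of xylem water potential at the root
#' collar: constant at the predawn value through the night, then a half-sine
#' descent from the predawn value at sunrise to the midday (minimum) value at
#' the trough hour, and a symmetric half-sine recovery reaching the predawn
#' value again at sunset.
#'
#' @param predawn predawn water potential, MPa (<= 0).
#' @param midday midday (minimum) water potential, MPa (<= predawn).
#' @param sunrise,trough,sunset hours of day (hour-ending convention);
#'   the trough must lie strictly between sunrise and sunset.
#' @param hours hours at which to evaluate (default 1:24).
#' @return numeric vector of collar water potentials, MPa.
#' @examples
#' collar_potential_series(-0.3, -0.7)
#' @export
collar_potential_series <- function(predawn, midday, sunrise = 6, trough = 14,
                                    sunset = 20, hours = 1:24) {
  if (!(midday <= predawn && predawn <= 0))
    stop("need midday <= predawn <= 0")
  if (!(trough > sunrise && trough < sunset))
    stop("trough hour must lie inside (sunrise, sunset)")
  amp <- predawn - midday
  psi <- rep(predawn, length(hours))
  down <- hours > sunrise & hours <= trough
  up <- hours > trough & hours < sunset
  psi[down] <- predawn - amp * sin(pi / 2 * (hours[down] - sunrise) /
                                     (trough - sunrise))
  psi[up] <- predawn - amp * sin(pi / 2 * (sunset - hours[up]) /
                                   (sunset - trough))
  psi
}

# clear-sky global radiation (W m-2) from solar elevation, with a fixed
# atmospheric transmissivity raised to the optical air mass
clearsky_radiation <- function(elevation, transmissivity = 0.75) {
  s <- sin(pmax(elevation, 0) * pi / 180)
  ifelse(s > 0, 1367 * transmissivity^(1 / pmax(s, 0.05)) * s, 0)
}

# stress-profile targets: end-of-season predawn/midday potentials (MPa)
.profile_targets <- list(
  NS = c(predawn = -0.30, midday = -0.70),
  LS = c(predawn = -0.70, midday = -1.50),
  MS = c(predawn = -1.20, midday = -2.20),
  SS = c(predawn = -1.80, midday = -2.80)
)

#' Generate a synthetic semi-arid season of forcing data
#'
#' Builds an hourly weather series (clear-sky radiation from solar geometry,
#' sinusoidal diurnal temperature with seeded day-to-day noise, humidity
#' anti-correlated with temperature, light wind) plus a daily water-potential
#' boundary series for one irrigation treatment. The seasonal temperature
#' profile is scaled so that cumulative degree-days over the season reach the
#' harvest total of 2,625 dd on the last day. The NS (no stress) profile
#' holds predawn potential near -0.3 MPa and midday near -0.7 MPa all season;
#' LS/MS/SS decline progressively after the stress onset day, and the
#' treatments are ordered NS >= LS >= MS >= SS at every date by construction
#' (the decline curves are deterministic).
#'
#' @param seed integer seed; the whole series is deterministic given it.
#' @param days season length in days (> 0). Default 150 (bloom to harvest).
#' @param profile one of "NS", "LS", "MS", "SS".
#' @param stress_onset day of season when the deficit treatments start to
#'   diverge (default 47: the mid-pit-hardening date for an end-of-April
#'   bloom).
#' @param stress_tau time constant (days) of the post-onset decline toward
#'   the profile's end-season severity.
#' @param start_date first (bloom) date.
#' @param params parameter set, for latitude, base temperature, harvest dd.
#' @return object of class \code{orchard_forcing}: list with \code{weather}
#'   (hourly data frame: date, hour, rad_Wm2, tair_C, rh_pct, wind_ms),
#'   \code{boundary} (daily: date, treatment, psi_predawn_MPa,
#'   psi_midday_MPa), \code{dd} (daily cumulative degree-days), and the
#'   generation settings.
#' @examples
#' f <- generate_synthetic_forcing(1, days = 10, profile = "NS")
#' range(f$weather$tair_C)
#' @export
generate_synthetic_forcing <- function(seed, days = 150,
                                       profile = c("NS", "LS", "MS", "SS"),
                                       stress_onset = 47, stress_tau = 20,
                                       start_date = as.Date("2011-04-26"),
                                       params = default_params()) {
  profile <- match.arg(profile)
  if (days <= 0) stop("season length must be positive")
  set.seed(as.integer(seed))
  dates <- start_date + seq_len(days) - 1
  doy <- as.integer(format(dates, "%j"))
  day_idx <- seq_len(days)

  # seasonal mean temperature: warms to a late-July plateau, then eases;
  # scaled below so the season ends exactly at the harvest degree-day total
  t_season <- 20 + 8 * sin(pi * pmin(day_idx / (0.75 * days), 1) / 1)
  t_noise <- stats::rnorm(days, 0, 1.2)
  tmean_raw <- t_season + t_noise
  base <- params$base_temp
  dd_raw <- sum(pmax(0, tmean_raw - base))
  scale <- params$harvest_dd / dd_raw
  tmean <- base + (tmean_raw - base) * scale   # all raw means exceed base
  dd <- accumulate_degree_days(dates, tmean, base)

  amp <- pmax(4, stats::rnorm(days, 7, 1))     # diurnal half-amplitude
  wind_day <- pmax(0.2, stats::rnorm(days, 1.5, 0.5))

  hour <- 1:24
  grid <- expand.grid(hour = hour, d = day_idx)
  el <- solar_position(params$latitude, doy[grid$d], grid$hour)$elevation
  rad <- clearsky_radiation(el, params$radiation$transmissivity)
  tair <- tmean[grid$d] + amp[grid$d] * cos(pi * (grid$hour - 15) / 12)
  rh <- pmin(95, pmax(15, 85 - 2.2 * (tair - 12) +
                        stats::rnorm(nrow(grid), 0, 2)))
  wind <- pmax(0.1, wind_day[grid$d] *
                 (0.6 + 0.8 * pmax(0, sin(pi * (grid$hour - 6) / 14))) +
                 stats::rnorm(nrow(grid), 0, 0.1))
  weather <- data.frame(
    date = dates[grid$d], hour = grid$hour,
    rad_Wm2 = round(rad, 2), tair_C = round(tair, 3),
    rh_pct = round(rh, 2), wind_ms = round(wind, 3)
  )

  # water potential boundary: deterministic decline curves after onset;
  # exponential approach to the end-season severity with a 30-day time
  # constant (deficit develops within weeks of withholding irrigation in a
  # semi-arid climate)
  tgt <- .profile_targets[[profile]]
  ns <- .profile_targets$NS
  ramp <- 1 - exp(-pmax(0, day_idx - stress_onset) / stress_tau)
  predawn <- ns["predawn"] + (tgt["predawn"] - ns["predawn"]) * ramp
  midday <- ns["midday"] + (tgt["midday"] - ns["midday"]) * ramp
  boundary <- data.frame(
    date = dates, treatment = profile,
    psi_predawn_MPa = as.numeric(predawn),
    psi_midday_MPa = as.numeric(midday)
  )

  out <- list(weather = weather, boundary = boundary,
              dd = data.frame(date = dates, dd = dd),
              profile = profile, seed = as.integer(seed), days = days,
              latitude = params$latitude, base_temp = base,
              stress_onset = stress_onset)
  class(out) <- c("orchard_forcing", "list")
  out
}

#' @export
print.orchard_forcing <- function(x, ...) {
  cat(sprintf("<orchard_forcing> %s profile, %d days (%s to %s), %d hourly records\n",
              x$profile, x$days, min(x$weather$date), max(x$weather$date),
              nrow(x$weather)))
  cat(sprintf("  final dd %.0f; predawn psi range [%.2f, %.2f] MPa\n",
              max(x$dd$dd), min(x$boundary$psi_predawn_MPa),
              max(x$boundary$psi_predawn_MPa)))
  invisible(x)
}

#' Read an hourly weather series from CSV
#'
#' Expected columns: \code{date,hour,rad_Wm2,tair_C,rh_pct,wind_ms}, one row
#' per hour. Rows violating physical ranges (negative radiation or wind,
#' relative humidity outside 0-100) or duplicated date-hour stamps are
#' reported with their row numbers.
#'
#' @param path CSV file path.
#' @return data frame of validated hourly records.
#' @export
read_forcing_csv <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "hour", "rad_Wm2", "tair_C", "rh_pct", "wind_ms")
  miss <- setdiff(need, names(w))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  w$date <- as.Date(w$date)
  bad <- which(w$rad_Wm2 < 0 | w$wind_ms < 0 |
                 w$rh_pct < 0 | w$rh_pct > 100 | !is.finite(w$tair_C))
  if (length(bad))
    stop("out-of-range values in rows: ", paste(bad, collapse = ", "))
  key <- paste(w$date, w$hour)
  if (anyDuplicated(key))
    stop("duplicated timestamps in rows: ",
         paste(which(duplicated(key)), collapse = ", "))
  w
}

#' Write an hourly weather series to CSV
#' @param weather data frame as returned by \code{read_forcing_csv} or found
#'   in \code{orchard_forcing$weather}.
#' @param path output file path.
#' @export
write_forcing_csv <- function(weather, path) {
  utils::write.csv(weather, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily water-potential boundary series from CSV
#'
#' Expected columns: \code{date,treatment,psi_predawn_MPa,psi_midday_MPa};
#' enforces midday <= predawn <= 0 per row.
#' @param path CSV file path.
#' @return data frame of validated daily boundary records.
#' @export
read_boundary_csv <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "treatment", "psi_predawn_MPa", "psi_midday_MPa")
  miss <- setdiff(need, names(b))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  b$date <- as.Date(b$date)
  bad <- which(!(b$psi_midday_MPa <= b$psi_predawn_MPa &
                   b$psi_predawn_MPa <= 0))
  if (length(bad))
    stop("potential ordering violated (need midday <= predawn <= 0) in rows: ",
         paste(bad, collapse = ", "))
  b
}
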