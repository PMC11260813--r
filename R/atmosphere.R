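#' Saturation vapour pressure
#'
#' Tetens-form exponential used throughout the FAO-56 chain:
#' `es(T) = 0.6108 * exp(17.27 T / (T + 237.3))` kPa. For daily values the
#' convention is the average of `es` at the daily extremes, see
#' [daily_saturation_vapour_pressure()].
#'
#' @param t Air temperature, degrees C (vectorised).
#' @return Saturation vapour pressure, kPa.
#' @examples saturation_vapour_pressure(20) # ~2.338 kPa
#' @export
saturation_vapour_pressure <- function(t) {
  stopifnot(all(t > -100, na.rm = TRUE))
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' Daily saturation vapour pressure from temperature extremes
#'
#' `es_day = (es(tmax) + es(tmin)) / 2`; using the mean temperature instead
#' underestimates es because of the curve's convexity.
#'
#' @param tmax,tmin Daily extreme temperatures, degrees C.
#' @return kPa.
#' @export
daily_saturation_vapour_pressure <- function(tmax, tmin) {
  (saturation_vapour_pressure(tmax) + saturation_vapour_pressure(tmin)) / 2
}

#' Slope of the saturation vapour-pressure curve
#'
#' `Delta = 4098 es(T) / (T + 237.3)^2`, evaluated at the daily mean
#' temperature in the daily energy-balance equations.
#'
#' @inheritParams saturation_vapour_pressure
#' @return kPa per degree C.
#' @export
slope_vapour_pressure_curve <- function(t) {
  4098 * saturation_vapour_pressure(t) / (t + 237.3)^2
}

#' Barometric pressure from elevation
#'
#' Standard-atmosphere relation `P = 101.3 ((293 - 0.0065 z)/293)^5.26` kPa,
#' used when the station does not report measured pressure.
#'
#' @param elevation Metres above sea level.
#' @return kPa.
#' @export
pressure_from_elevation <- function(elevation) {
  101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
}

#' Psychrometric constant
#'
#' `gamma = 0.665e-3 P` kPa per degree C, proportional to air pressure.
#'
#' @param pressure Barometric pressure, kPa (> 0).
#' @return kPa per degree C.
#' @export
psychrometric_constant <- function(pressure) {
  stopifnot(all(pressure > 0, na.rm = TRUE))
  0.665e-3 * pressure
}

#' Actual vapour pressure
#'
#' Prefers the measured mean vapour pressure when available; otherwise
#' derives it from mean relative humidity as `ea = RH/100 * es_day`. The
#' result is clamped to `[0, es_day]` so derived humidity can never exceed
#' saturation.
#'
#' @param vp_kpa Measured vapour pressure, kPa, or `NA`.
#' @param rh_pct Mean relative humidity, percent, or `NA`.
#' @param tmax,tmin Daily temperature extremes, degrees C (needed for the
#'   RH route and for the saturation clamp).
#' @return kPa (vectorised; `NA` where both sources are missing is an error).
#' @export
actual_vapour_pressure <- function(vp_kpa, rh_pct, tmax, tmin) {
  n <- max(length(vp_kpa), length(rh_pct), length(tmax), length(tmin))
  vp_kpa <- rep_len(vp_kpa, n); rh_pct <- rep_len(rh_pct, n)
  tmax <- rep_len(tmax, n); tmin <- rep_len(tmin, n)
  if (any(is.na(vp_kpa) & is.na(rh_pct)))
    stop("actual vapour pressure needs vp_kpa or rh_pct", call. = FALSE)
  es_day <- daily_saturation_vapour_pressure(tmax, tmin)
  ea <- ifelse(is.na(vp_kpa), rh_pct / 100 * es_day, vp_kpa)
  pmin(pmax(ea, 0), es_day)
}

#' Extraterrestrial radiation and astronomical day length
#'
#' Top-of-atmosphere solar radiation for a latitude and date from the
#' standard solar geometry: inverse relative Earth-Sun distance, solar
#' declination and sunset hour angle. Beyond the polar circles the hour
#' angle is clamped, giving Ra = 0 and day length 0 (polar night) or 24 h
#' (midnight sun).
#'
#' @param latitude Decimal degrees.
#' @param date `Date` vector, or integer day-of-year (1-366).
#' @return A data frame with columns `Ra` (MJ m-2 day-1) and `daylength`
#'   (hours, `24 ws / pi`).
#' @examples
#' extraterrestrial_radiation(-20, 246) # Ra ~ 32.2 MJ m-2 day-1
#' @export
extraterrestrial_radiation <- function(latitude, date) {
  J <- if (inherits(date, "Date")) as.POSIXlt(date)$yday + 1L else as.integer(date)
  stopifnot(all(J >= 1L & J <= 366L))
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * J / 365)
  dec <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(dec))))
  Gsc <- 0.0820 # MJ m-2 min-1
  Ra <- 24 * 60 / pi * Gsc * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  data.frame(Ra = pmax(Ra, 0), daylength = 24 * ws / pi)
}

#' Incoming shortwave radiation from sunshine duration
#'
#' Angstrom-Prescott relation `Rs = (as + bs n/N) Ra` with the FAO-56
#' default coefficients `as = 0.25`, `bs = 0.50` (no local calibration
#' available). `n` is clipped to `N` with a warning when measured sunshine
#' exceeds the astronomical day length.
#'
#' @param Ra Extraterrestrial radiation, MJ m-2 day-1.
#' @param n Measured sunshine duration, hours.
#' @param N Astronomical day length, hours.
#' @param as,bs Angstrom coefficients.
#' @return Rs, MJ m-2 day-1.
#' @export
shortwave_from_sunshine <- function(Ra, n, N, as = 0.25, bs = 0.50) {
  if (any(N <= 0 & n > 0, na.rm = TRUE))
    stop("sunshine recorded on a day with zero day length", call. = FALSE)
  if (any(n > N + 1e-9, na.rm = TRUE)) {
    warning("sunshine hours exceed day length; clipping to N", call. = FALSE)
    n <- pmin(n, N)
  }
  ratio <- ifelse(N > 0, n / N, 0)
  (as + bs * ratio) * Ra
}

#' Net radiation at the reference surface
#'
#' `Rn = Rns - Rnl` with shortwave `Rns = (1 - 0.23) Rs` (fixed grass albedo)
#' and longwave `Rnl` from the Stefan-Boltzmann law at the daily extreme
#' temperatures with humidity (`0.34 - 0.14 sqrt(ea)`) and cloudiness
#' (`1.35 Rs/Rso - 0.35`) corrections; clear-sky radiation
#' `Rso = (0.75 + 2e-5 z) Ra`. The relative shortwave ratio `Rs/Rso` is
#' clamped to `[0.3, 1]`, which also guards the polar-night case `Ra ~ 0`.
#'
#' @param Rs Incoming shortwave, MJ m-2 day-1.
#' @param Ra Extraterrestrial radiation, MJ m-2 day-1.
#' @param ea Actual vapour pressure, kPa.
#' @param tmax,tmin Daily temperature extremes, degrees C.
#' @param elevation Station elevation, m.
#' @return Rn, MJ m-2 day-1 (can be negative on overcast winter days).
#' @export
net_radiation <- function(Rs, Ra, ea, tmax, tmin, elevation) {
  Rns <- (1 - 0.23) * Rs
  Rso <- (0.75 + 2e-5 * elevation) * Ra
  rel <- ifelse(Rso > 0, Rs / Rso, 0.3)
  rel <- pmin(pmax(rel, 0.3), 1)
  sigma <- 4.903e-9 # MJ K-4 m-2 day-1
  Rnl <- sigma * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel - 0.35)
  Rns - Rnl
}

#' Wind speed at 2 m
#'
#' Logarithmic wind-profile conversion from the measurement height `z`:
#' `u2 = u * 4.87 / log(67.8 z - 5.42)`; identity at `z = 2`.
#'
#' @param u Wind speed at height `z`, m s-1.
#' @param z Measurement height, m (> 0.08 so the log argument is positive).
#' @return m s-1.
#' @export
wind_at_2m <- function(u, z) {
  stopifnot(all(z > 0.08))
  ifelse(abs(z - 2) < 1e-12, u, u * 4.87 / log(67.8 * z - 5.42))
}

#' Daily atmospheric state for a weather series
#'
#' Computes, for every day of a [weather_series()], the psychrometric and
#' radiation quantities the ET0 models consume: `es`, `ea`, `delta`,
#' `gamma`, `Ra`, `daylength`, `Rs`, `Rn`, `G` (zero at daily scale) and
#' `u2`. Station pressure is used when reported, otherwise it is derived
#' from elevation.
#'
#' @param series A `weather_series`.
#' @return A data frame, one row per day, columns
#'   `date, es, ea, delta, gamma, Ra, daylength, Rs, Rn, G, u2`.
#' @export
atmospheric_state <- function(series) {
  stopifnot(inherits(series, "weather_series"))
  st <- attr(series, "station")
  if (!nrow(series)) {
    out <- data.frame(date = as.Date(character()), es = numeric(),
                      ea = numeric(), delta = numeric(), gamma = numeric(),
                      Ra = numeric(), daylength = numeric(), Rs = numeric(),
                      Rn = numeric(), G = numeric(), u2 = numeric())
    return(out)
  }
  es <- daily_saturation_vapour_pressure(series$tmax_c, series$tmin_c)
  ea <- actual_vapour_pressure(series$vp_kpa, series$rh_pct,
                               series$tmax_c, series$tmin_c)
  delta <- slope_vapour_pressure_curve(series$tmean_c)
  pres <- ifelse(is.na(series$pressure_kpa),
                 pressure_from_elevation(st$elevation), series$pressure_kpa)
  gamma <- psychrometric_constant(pres)
  geo <- extraterrestrial_radiation(st$latitude, series$date)
  Rs <- shortwave_from_sunshine(geo$Ra, series$sunshine_h, geo$daylength)
  Rn <- net_radiation(Rs, geo$Ra, ea, series$tmax_c, series$tmin_c,
                      st$elevation)
  u2 <- wind_at_2m(series$wind_ms, st$anemometer_height)
  data.frame(date = series$date, es = es, ea = ea, delta = delta,
             gamma = gamma, Ra = geo$Ra, daylength = geo$daylength,
             Rs = Rs, Rn = Rn, G = 0, u2 = u2)
}
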