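#' Climate specification for the synthetic weather generator
#'
#' Parameters of a stylised temperate semi-humid/semiarid continental
#' monsoon station of the kind found on the Haihe Plain: cold dry winters,
#' hot summers with rainfall concentrated in June-September, and a marked
#' annual sunshine cycle. Defaults describe such a station (around 39
#' degrees N, near sea level, ~13 degrees C annual mean with a ~14.5 degree
#' seasonal half-amplitude, ~500 mm annual rainfall of which ~70% falls in
#' summer).
#'
#' @param latitude,elevation Station geography (degrees, m).
#' @param tmean_annual Annual mean temperature, degrees C.
#' @param tmean_amplitude Half-amplitude of the annual temperature
#'   sinusoid, degrees C.
#' @param diurnal_range_mean Mean daily temperature range, degrees C.
#' @param rh_mean Mean relative humidity, percent.
#' @param wind_mean Mean wind speed at the anemometer, m s-1.
#' @param sunshine_fraction_mean Mean relative sunshine duration n/N,
#'   in (0, 1).
#' @param annual_precip_mean Expected annual precipitation, mm.
#' @param precip_summer_fraction Fraction of annual rainfall concentrated
#'   in the summer bump, in (0, 1).
#' @param noise_sd_t Standard deviation of the AR(1) temperature noise,
#'   degrees C.
#' @param ar1_phi AR(1) autocorrelation of the temperature noise.
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @return An object of class `climate_spec`.
#' @export
climate_spec <- function(latitude = 38.85, elevation = 17,
                         tmean_annual = 13, tmean_amplitude = 14.5,
                         diurnal_range_mean = 10, rh_mean = 60,
                         wind_mean = 2.2, sunshine_fraction_mean = 0.55,
                         annual_precip_mean = 500,
                         precip_summer_fraction = 0.7,
                         noise_sd_t = 2, ar1_phi = 0.7, seed = 42L) {
  stopifnot(tmean_amplitude > 0, diurnal_range_mean > 0, rh_mean > 0,
            rh_mean < 100, wind_mean > 0,
            sunshine_fraction_mean > 0, sunshine_fraction_mean < 1,
            annual_precip_mean > 0,
            precip_summer_fraction > 0, precip_summer_fraction < 1,
            noise_sd_t >= 0, abs(ar1_phi) < 1)
  structure(as.list(environment()), class = "climate_spec")
}

# evaluate f() under a private RNG stream, restoring the caller's state
with_seed <- function(seed, f) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  f()
}

#' Generate a synthetic daily weather series
#'
#' Simulates `n_years` of daily station weather consistent with the
#' [climate_spec()]: a temperature sinusoid peaking in mid-July (Northern
#' Hemisphere) plus AR(1) noise, a positive diurnal range around its mean,
#' sunshine hours as a noisy fraction of the astronomical day length
#' (always within `[0, N]`), seasonal relative humidity confined to
#' (5, 100), gamma-distributed positive wind speeds, and rainfall whose
#' daily expectation splits the annual mean between a uniform background
#' and a Gaussian summer bump centred on mid-July. Every generated series
#' passes [weather_series()] validation, and a fixed seed reproduces the
#' series exactly.
#'
#' @param spec A [climate_spec()].
#' @param n_years Number of calendar years (>= 1).
#' @param start_year First calendar year.
#' @param station_id Identifier for the generated station.
#' @return A [weather_series()].
#' @export
generate_station_weather <- function(spec, n_years, start_year = 2000L,
                                     station_id = "synthetic") {
  stopifnot(inherits(spec, "climate_spec"), n_years >= 1)
  station <- station_meta(station_id, spec$latitude, spec$elevation)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1L)),
               by = "day")
  n <- length(dates)
  doy <- as.POSIXlt(dates)$yday + 1
  # mid-July peak in the NH, mid-January in the SH
  phase <- if (spec$latitude >= 0) 196 else 15
  seasonal <- cos(2 * pi * (doy - phase) / 365.25)

  df <- with_seed(spec$seed, function() {
    eps <- stats::rnorm(n, 0, spec$noise_sd_t * sqrt(1 - spec$ar1_phi^2))
    ar <- stats::filter(eps, spec$ar1_phi, method = "recursive")
    tmean <- spec$tmean_annual + spec$tmean_amplitude * seasonal +
      as.numeric(ar)
    half <- pmax(1, stats::rnorm(n, spec$diurnal_range_mean, 2)) / 2
    tmax <- tmean + half
    tmin <- tmean - half

    geo <- extraterrestrial_radiation(spec$latitude, dates)
    frac <- pmin(pmax(stats::rnorm(n, spec$sunshine_fraction_mean, 0.18),
                      0), 1)
    sunshine <- frac * geo$daylength

    rh <- pmin(pmax(spec$rh_mean + 12 * cos(2 * pi * (doy - 227) / 365.25) +
                      stats::rnorm(n, 0, 8), 6), 99)
    wind <- stats::rgamma(n, shape = 4, scale = spec$wind_mean / 4)

    bump <- exp(-((doy - 196) / 40)^2)
    # expected mm on each day; bump mass normalised within the year
    year <- format(dates, "%Y")
    bump_norm <- stats::ave(bump, year, FUN = function(b) b / sum(b))
    ndays_year <- stats::ave(rep(1, n), year, FUN = sum)
    mu <- spec$annual_precip_mean *
      ((1 - spec$precip_summer_fraction) / ndays_year +
         spec$precip_summer_fraction * bump_norm)
    p_wet <- 0.35
    wet <- stats::runif(n) < p_wet
    precip <- ifelse(wet, stats::rexp(n, rate = 1) * mu / p_wet, 0)

    data.frame(date = dates, tmax_c = tmax, tmin_c = tmin, tmean_c = tmean,
               rh_pct = rh, vp_kpa = NA_real_,
               pressure_kpa = pressure_from_elevation(spec$elevation),
               wind_ms = wind, sunshine_h = sunshine, precip_mm = precip)
  })
  weather_series(df, station)
}

#' Planted-truth ET0 series for calibration recovery tests
#'
#' Generates a daily "standard" ET0 series that is exactly affine in the
#' FAO-24 Radiation driver, `et0 = a_true + b_true * driver + noise`, with
#' Gaussian noise of standard deviation `noise_sd` and a non-negativity
#' clamp. Substituted for the Penman-Monteith standard in
#' [calibrate_fr()] recovery tests, where the true coefficients are known.
#'
#' @param weather A [weather_series()].
#' @param a_true,b_true True coefficients.
#' @param noise_sd Noise standard deviation, mm day-1.
#' @param params An [et0_params()] (sets the driver unit convention).
#' @param seed Integer seed for the noise.
#' @return A daily [et0_series()] with model label `"FR_truth"`.
#' @export
generate_fr_truth <- function(weather, a_true, b_true, noise_sd = 0,
                              params = et0_params(), seed = 1L) {
  driver <- fr_driver(weather, params)
  noise <- if (noise_sd > 0) {
    with_seed(seed, function() stats::rnorm(length(driver), 0, noise_sd))
  } else rep(0, length(driver))
  et0_series(weather$date, pmax(a_true + b_true * driver + noise, 0),
             model = "FR_truth", scale = "daily")
}
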