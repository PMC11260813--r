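# shared fixtures: a mid-latitude station and small handmade weather tables

demo_station <- function() station_meta("demo", latitude = 38.85, elevation = 17)

# a well-formed n-day weather data frame starting at `start`
make_weather_df <- function(n = 3, start = "2001-06-01", tmean = 20,
                            range = 10, rh = 60, wind = 2, sun = 8,
                            precip = 0) {
  dates <- seq(as.Date(start), by = "day", length.out = n)
  r <- function(x) rep_len(x, n)
  data.frame(date = dates,
             tmax_c = r(tmean + range / 2), tmin_c = r(tmean - range / 2),
             tmean_c = r(tmean), rh_pct = r(rh), vp_kpa = r(NA_real_),
             pressure_kpa = r(NA_real_), wind_ms = r(wind),
             sunshine_h = r(sun), precip_mm = r(precip))
}

make_series <- function(...) weather_series(make_weather_df(...), demo_station())

# one seeded synthetic year reused across tests (generation is cheap)
synthetic_year <- function(seed = 11L, n_years = 1L, start_year = 2001L) {
  generate_station_weather(climate_spec(seed = seed), n_years = n_years,
                           start_year = start_year)
}

with_seed_local <- function(seed, f) withr::with_seed(seed, f())

# independent straight-line re-implementation of the iterative
# posterior-mean calibration; deliberately shares no code with calibrate_fr
oracle_calibrate <- function(pm, driver, prior_a = 0.18, prior_b = 0.50,
                             w = 0.812, tol = 1e-6, max_iter = 100,
                             min_driver = 0.05) {
  keep <- driver >= min_driver
  pm <- pm[keep]; driver <- driver[keep]
  a <- prior_a; b <- prior_b
  for (it in seq_len(max_iter)) {
    bs <- (pm - a) / driver
    b_new <- (prior_b * var(bs) + mean(bs) * w) / (var(bs) + w)
    as_ <- pm - b_new * driver
    a_new <- (prior_a * var(as_) + mean(as_) * w) / (var(as_) + w)
    if (max(abs(a_new - a), abs(b_new - b)) < tol) {
      a <- a_new; b <- b_new
      break
    }
    a <- a_new; b <- b_new
  }
  list(a = a, b = b, iterations = it)
}

# independent Pearson III quantile oracle: numeric inversion of the CDF
# obtained by integrating the density written from its closed form
oracle_p3_quantile <- function(mean, cv, cs, p_exceed) {
  alpha <- 4 / cs^2
  beta <- mean * cv * cs / 2
  x0 <- mean * (1 - 2 * cv / cs)
  dens <- function(x) {
    z <- (x - x0) / beta
    ifelse(z <= 0, 0, z^(alpha - 1) * exp(-z) / (beta * gamma(alpha)))
  }
  cdf <- function(x) integrate(dens, x0, x, rel.tol = 1e-12,
                               subdivisions = 2000L)$value
  target <- 1 - p_exceed
  lo <- x0 + 1e-12
  hi <- mean * (1 + 20 * cv)
  uniroot(function(x) cdf(x) - target, c(lo, hi), tol = 1e-10)$root
}
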