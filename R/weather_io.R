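#' Station metadata
#'
#' Describes the fixed properties of a weather station that drive radiation
#' geometry and unit conversions: latitude (solar geometry), elevation
#' (pressure and clear-sky radiation) and the anemometer height (log-profile
#' wind conversion to 2 m).
#'
#' @param station_id Character scalar identifying the station.
#' @param latitude Decimal degrees in \[-90, 90\]; positive north.
#' @param elevation Metres above sea level; must be >= -430 (the lowest land
#'   surface on Earth).
#' @param anemometer_height Height of the wind measurement in metres (> 0).
#'   Defaults to the 10 m synoptic standard.
#'
#' @return An object of class `station_meta`.
#' @examples
#' station_meta("demo", latitude = 38.85, elevation = 17)
#' @export
station_meta <- function(station_id, latitude, elevation,
                         anemometer_height = 10) {
  stopifnot(is.character(station_id), length(station_id) == 1L)
  latitude <- as.numeric(latitude)
  elevation <- as.numeric(elevation)
  anemometer_height <- as.numeric(anemometer_height)
  if (!is.finite(latitude) || latitude < -90 || latitude > 90)
    stop("latitude must lie in [-90, 90]", call. = FALSE)
  if (!is.finite(elevation) || elevation < -430)
    stop("elevation must be >= -430 m", call. = FALSE)
  if (!is.finite(anemometer_height) || anemometer_height <= 0)
    stop("anemometer_height must be > 0", call. = FALSE)
  structure(
    list(station_id = station_id, latitude = latitude,
         elevation = elevation, anemometer_height = anemometer_height),
    class = "station_meta")
}

#' @export
print.station_meta <- function(x, ...) {
  cat(sprintf("<station_meta> %s  lat %.4f deg  elev %.1f m  anemometer %.1f m\n",
              x$station_id, x$latitude, x$elevation, x$anemometer_height))
  invisible(x)
}

# canonical column order used by read/write and the validator
weather_columns <- function() {
  c("date", "tmax_c", "tmin_c", "tmean_c", "rh_pct", "vp_kpa",
    "pressure_kpa", "wind_ms", "sunshine_h", "precip_mm")
}

#' Assemble and validate a daily weather series
#'
#' Binds a data frame of daily records to its station metadata after checking
#' the physical invariants every downstream module relies on: strictly
#' increasing dates, `tmin <= tmean <= tmax`, relative humidity in (0, 100],
#' non-negative wind, sunshine and precipitation, and at least one humidity
#' source (`rh_pct` or `vp_kpa`) per day. Canonical units are fixed here:
#' degrees Celsius, kPa, m s-1, hours, mm; no conversion happens at I/O.
#'
#' Gaps between consecutive dates are allowed (e.g. between years) but
#' recorded in the `gaps` attribute so aggregation can flag incomplete
#' periods.
#'
#' @param records Data frame with the canonical columns (see
#'   [read_weather_table()] for the list); `date` is coerced with `as.Date`.
#' @param station A [station_meta()] object.
#'
#' @return A data frame of class `weather_series` with attributes `station`
#'   and `gaps` (a `Date` vector of dates after which a within-record gap
#'   starts).
#' @export
weather_series <- function(records, station) {
  stopifnot(inherits(station, "station_meta"), is.data.frame(records))
  cols <- weather_columns()
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("missing weather columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  records <- as.data.frame(records)[cols]
  records$date <- as.Date(records$date)
  for (nm in setdiff(cols, "date")) records[[nm]] <- as.numeric(records[[nm]])

  if (nrow(records)) {
    if (anyNA(records$date)) stop("unparseable dates present", call. = FALSE)
    if (is.unsorted(records$date, strictly = TRUE))
      stop("dates must be strictly increasing with no duplicates",
           call. = FALSE)
    problems <- validate_weather_rows(records)
    if (length(problems))
      stop("invalid weather rows:\n  ", paste(problems, collapse = "\n  "),
           call. = FALSE)
  }
  d <- records$date
  gaps <- if (length(d) > 1L) d[which(diff(as.integer(d)) > 1L)] else as.Date(character())
  structure(records, station = station, gaps = gaps,
            class = c("weather_series", "data.frame"))
}

# returns a character vector of row-level diagnostics, empty when clean
validate_weather_rows <- function(df) {
  msg <- character()
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) sprintf("%s: %s", format(df$date[i]), what) else character()
  }
  with_t <- !is.na(df$tmax_c) & !is.na(df$tmin_c)
  msg <- c(msg, bad(with_t & df$tmin_c > df$tmax_c, "tmin > tmax"))
  with_m <- with_t & !is.na(df$tmean_c)
  msg <- c(msg, bad(with_m & (df$tmean_c > df$tmax_c + 1e-9 |
                              df$tmean_c < df$tmin_c - 1e-9),
                    "tmean outside [tmin, tmax]"))
  msg <- c(msg, bad(!is.na(df$rh_pct) & (df$rh_pct <= 0 | df$rh_pct > 100),
                    "rh_pct outside (0, 100]"))
  msg <- c(msg, bad(!is.na(df$vp_kpa) & df$vp_kpa < 0, "vp_kpa < 0"))
  msg <- c(msg, bad(!is.na(df$wind_ms) & df$wind_ms < 0, "wind_ms < 0"))
  msg <- c(msg, bad(!is.na(df$sunshine_h) & df$sunshine_h < 0, "sunshine_h < 0"))
  msg <- c(msg, bad(!is.na(df$precip_mm) & df$precip_mm < 0, "precip_mm < 0"))
  msg <- c(msg, bad(is.na(df$rh_pct) & is.na(df$vp_kpa),
                    "neither rh_pct nor vp_kpa present"))
  msg
}

#' Read a daily weather table
#'
#' Reads a delimited text file with header columns
#' `date,tmax_c,tmin_c,tmean_c,rh_pct,vp_kpa,pressure_kpa,wind_ms,sunshine_h,precip_mm`
#' (comma-separated, UTF-8) and returns a validated [weather_series()].
#' Empty strings and `"NA"` (plus any extra `na` tokens) become missing
#' values. Unknown columns are a hard error; row-level invariant violations
#' are reported with their dates.
#'
#' @param path Path to the CSV file.
#' @param station A [station_meta()] object.
#' @param na Missing-value tokens.
#' @return A `weather_series`.
#' @seealso [write_weather_table()]
#' @export
read_weather_table <- function(path, station, na = c("", "NA")) {
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = na, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!nrow(df) && !ncol(df)) stop("empty weather file: ", path, call. = FALSE)
  unknown <- setdiff(names(df), weather_columns())
  if (length(unknown))
    stop("unknown columns in ", path, ": ", paste(unknown, collapse = ", "),
         call. = FALSE)
  weather_series(df, station)
}

#' Write a daily weather table
#'
#' Writes the canonical CSV form of a weather series: canonical column order,
#' ISO-8601 dates, missing values as empty strings. `read_weather_table()`
#' of the written file reproduces the series exactly up to float formatting
#' (values are printed with 15 significant digits, well inside the 1e-9
#' round-trip tolerance).
#'
#' @param series A `weather_series`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_weather_table <- function(series, path) {
  stopifnot(inherits(series, "weather_series"))
  out <- as.data.frame(series)[weather_columns()]
  out$date <- format(out$date, "%Y-%m-%d")
  for (nm in setdiff(names(out), "date"))
    out[[nm]] <- ifelse(is.na(out[[nm]]), "",
                        formatC(out[[nm]], digits = 15, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.weather_series <- function(x, ...) {
  st <- attr(x, "station")
  cat(sprintf("<weather_series> %d days, station %s (lat %.2f, elev %.0f m)\n",
              nrow(x), st$station_id, st$latitude, st$elevation))
  if (nrow(x))
    cat(sprintf("  %s .. %s, %d within-record gap(s)\n",
                format(min(x$date)), format(max(x$date)),
                length(attr(x, "gaps"))))
  NextMethod()
}
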