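#' Empirical model parameters
#'
#' Collects the empirical coefficients of the four simplified ET0 models
#' with their conventional defaults: the Priestley-Taylor coefficient
#' `pt_alpha = 1.26`, the Hargreaves conversion factor `ha_c0 = 0.0023`,
#' the McCloud constants `mc_k = 0.254` mm day-1 and `mc_w = 1.07`, and the
#' FAO-24 Radiation coefficients `fr_a = 0.18` mm day-1 and `fr_b = 0.50`.
#'
#' `radiation_in_mm` controls whether radiation terms entering the
#' Priestley-Taylor, Hargreaves and FAO-24 Radiation equations are first
#' converted from MJ m-2 day-1 to mm day-1 of evaporation equivalent by the
#' latent-heat factor 0.408 (default; dimensionally consistent with the
#' 0.408 in the Penman-Monteith equation). Setting it `FALSE` computes the
#' literal textbook forms with radiation in MJ m-2 day-1.
#'
#' @param pt_alpha,ha_c0,mc_k,mc_w,fr_a,fr_b Model coefficients (all > 0).
#' @param radiation_in_mm Logical; apply the 0.408 MJ-to-mm conversion.
#' @return An object of class `et0_params`.
#' @export
et0_params <- function(pt_alpha = 1.26, ha_c0 = 0.0023, mc_k = 0.254,
                       mc_w = 1.07, fr_a = 0.18, fr_b = 0.50,
                       radiation_in_mm = TRUE) {
  vals <- c(pt_alpha = pt_alpha, ha_c0 = ha_c0, mc_k = mc_k, mc_w = mc_w,
            fr_a = fr_a, fr_b = fr_b)
  # fr_a is an additive offset in mm day-1 and may legitimately come out
  # negative from calibration (the original FAO-24 intercept is -0.3);
  # the multiplicative coefficients must stay strictly positive
  if (any(!is.finite(vals)))
    stop("all model coefficients must be finite", call. = FALSE)
  if (any(vals[setdiff(names(vals), "fr_a")] <= 0))
    stop("model coefficients other than fr_a must be strictly positive",
         call. = FALSE)
  structure(c(as.list(vals), list(radiation_in_mm = isTRUE(radiation_in_mm))),
            class = "et0_params")
}

# MJ m-2 day-1 -> mm day-1 evaporation equivalent (lambda = 2.45 MJ kg-1)
MJ_TO_MM <- 0.408

mj_to_mm <- function(x, params) if (params$radiation_in_mm) MJ_TO_MM * x else x

et0_model_labels <- function() c("PM", "PT", "HA", "MC", "FR")

#' ET0 series container
#'
#' A dated series of ET0 values labelled by model and time scale. Daily
#' periods are `Date`s; dekad and monthly periods are character labels
#' (`"YYYY-MM-d1"`..`"d3"` and `"YYYY-MM"`).
#'
#' @param period Period labels (Date for daily).
#' @param et0_mm ET0 in mm per period.
#' @param model Model label, e.g. `"PM"`, `"FR"`, `"FR_calibrated"`.
#' @param scale One of `"daily"`, `"dekad"`, `"monthly"`.
#' @return Data frame of class `et0_series` with attributes `model`, `scale`.
#' @export
et0_series <- function(period, et0_mm, model, scale = "daily") {
  scale <- match.arg(scale, c("daily", "dekad", "monthly"))
  stopifnot(length(period) == length(et0_mm))
  structure(data.frame(period = period, et0_mm = as.numeric(et0_mm)),
            model = model, scale = scale,
            class = c("et0_series", "data.frame"))
}

#' @export
print.et0_series <- function(x, ...) {
  cat(sprintf("<et0_series> model %s, %s scale, %d periods\n",
              attr(x, "model"), attr(x, "scale"), nrow(x)))
  NextMethod()
}

clamp0 <- function(x) pmax(x, 0)

#' FAO-56 Penman-Monteith reference evapotranspiration
#'
#' The combination equation used as the standard throughout the package:
#' `ET0 = (0.408 Delta (Rn - G) + gamma 900/(T+273) u2 (es - ea)) /
#' (Delta + gamma (1 + 0.34 u2))` with `T = tmean` and `G = 0` at daily
#' scale. Negative values (rare radiative-deficit winter days) are clamped
#' to zero.
#'
#' @param series A [weather_series()] (any number of rows).
#' @param atm Optional precomputed [atmospheric_state()]; recomputed when
#'   `NULL`.
#' @return Numeric vector of daily ET0, mm day-1.
#' @export
et0_penman_monteith <- function(series, atm = NULL) {
  if (is.null(atm)) atm <- atmospheric_state(series)
  t <- series$tmean_c
  num <- 0.408 * atm$delta * (atm$Rn - atm$G) +
    atm$gamma * 900 / (t + 273) * atm$u2 * (atm$es - atm$ea)
  clamp0(num / (atm$delta + atm$gamma * (1 + 0.34 * atm$u2)))
}

#' Priestley-Taylor ET0
#'
#' Radiation-driven model `ET0 = alpha * Delta/(Delta+gamma) * (Rn - G)`
#' (converted to mm day-1), needing neither wind nor humidity beyond the
#' longwave correction.
#'
#' @inheritParams et0_penman_monteith
#' @param params An [et0_params()] object.
#' @return mm day-1.
#' @export
et0_priestley_taylor <- function(series, params = et0_params(), atm = NULL) {
  if (is.null(atm)) atm <- atmospheric_state(series)
  clamp0(params$pt_alpha * atm$delta / (atm$delta + atm$gamma) *
           mj_to_mm(atm$Rn - atm$G, params))
}

#' Hargreaves ET0
#'
#' Temperature-based model
#' `ET0 = C0 * Ra * (Tmean + 17.8) * sqrt(Tmax - Tmin)` with Ra in mm day-1
#' evaporation equivalent.
#'
#' @inheritParams et0_priestley_taylor
#' @return mm day-1.
#' @export
et0_hargreaves <- function(series, params = et0_params(), atm = NULL) {
  if (any(series$tmax_c < series$tmin_c, na.rm = TRUE))
    stop("tmax < tmin", call. = FALSE)
  if (is.null(atm)) atm <- atmospheric_state(series)
  clamp0(params$ha_c0 * mj_to_mm(atm$Ra, params) *
           (series$tmean_c + 17.8) * sqrt(series$tmax_c - series$tmin_c))
}

#' McCloud ET0
#'
#' Purely thermal exponential model `ET0 = K * W^(1.8 Tmean)`; always
#' positive and strictly increasing in temperature.
#'
#' @inheritParams et0_priestley_taylor
#' @return mm day-1.
#' @export
et0_mccloud <- function(series, params = et0_params()) {
  params$mc_k * params$mc_w^(1.8 * series$tmean_c)
}

#' FAO-24 Radiation ET0
#'
#' Makkink-family model `ET0 = a + b * Delta/(Delta+gamma) * Rs` with Rs in
#' mm day-1 evaporation equivalent. The default coefficients
#' `(a, b) = (0.18, 0.50)` are the ones recalibrated by
#' [calibrate_fr()].
#'
#' @inheritParams et0_priestley_taylor
#' @return mm day-1.
#' @export
et0_fao24_radiation <- function(series, params = et0_params(), atm = NULL) {
  if (is.null(atm)) atm <- atmospheric_state(series)
  clamp0(params$fr_a + params$fr_b * fr_driver(series, params, atm))
}

#' Radiation driver of the FAO-24 Radiation model
#'
#' The term the coefficient `b` multiplies: `Delta/(Delta+gamma) * Rs`
#' (mm day-1 equivalent under the default unit convention). Exposed because
#' the Bayesian calibration inverts the model around it.
#'
#' @inheritParams et0_priestley_taylor
#' @return Numeric vector, mm day-1.
#' @export
fr_driver <- function(series, params = et0_params(), atm = NULL) {
  if (is.null(atm)) atm <- atmospheric_state(series)
  atm$delta / (atm$delta + atm$gamma) * mj_to_mm(atm$Rs, params)
}

#' Compute a daily ET0 series for one model
#'
#' Dispatches to one of the five model implementations and wraps the result
#' as a daily [et0_series()].
#'
#' @param series A [weather_series()].
#' @param model `"PM"`, `"PT"`, `"HA"`, `"MC"` or `"FR"`.
#' @param params An [et0_params()] object.
#' @return A daily `et0_series`.
#' @examples
#' st <- station_meta("demo", 38.85, 17)
#' w <- generate_station_weather(climate_spec(seed = 1), n_years = 1)
#' head(compute_et0(w, "PM"))
#' @export
compute_et0 <- function(series, model, params = et0_params()) {
  model <- match.arg(toupper(model), et0_model_labels())
  vals <- switch(model,
    PM = et0_penman_monteith(series),
    PT = et0_priestley_taylor(series, params),
    HA = et0_hargreaves(series, params),
    MC = et0_mccloud(series, params),
    FR = et0_fao24_radiation(series, params))
  et0_series(series$date, vals, model = model, scale = "daily")
}
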