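#' Empirical cumulative frequency of a ranked year
#'
#' Weibull plotting position `p = m / (N + 1)` for the year ranked `m`-th
#' when annual rainfall is sorted in descending order; `p` is therefore an
#' exceedance frequency (small `p` = wet year).
#'
#' @param m Rank (1-based), 1 = wettest year.
#' @param n_years Total number of years.
#' @return Probability in (0, 1).
#' @export
cumulative_frequency <- function(m, n_years) {
  stopifnot(all(m >= 1), all(m <= n_years))
  m / (n_years + 1)
}

#' Annual precipitation totals
#'
#' Sums daily precipitation by calendar year. Years with flagged
#' within-year gaps are dropped with a warning, since their totals would be
#' biased low.
#'
#' @param series A [weather_series()].
#' @return Data frame `year, precip_mm`, one row per complete year.
#' @export
annual_precipitation <- function(series) {
  stopifnot(inherits(series, "weather_series"))
  yr <- as.integer(format(series$date, "%Y"))
  tot <- tapply(series$precip_mm, yr, sum)
  out <- data.frame(year = as.integer(names(tot)),
                    precip_mm = as.numeric(tot))
  gap_years <- unique(as.integer(format(attr(series, "gaps"), "%Y")))
  if (length(gap_years)) {
    warning("dropping years with within-year gaps: ",
            paste(gap_years, collapse = ", "), call. = FALSE)
    out <- out[!out$year %in% gap_years, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Fit a Pearson Type III distribution by moments
#'
#' Method-of-moments fit of the three-parameter gamma family standard in
#' hydrological frequency analysis: mean, coefficient of variation
#' `cv = sd/mean`, and bias-corrected sample skew `cs`. A skew whose
#' magnitude falls below 1e-6 is floored (with its sign) to avoid the
#' degenerate shape parameter `4/cs^2`.
#'
#' @param precip Numeric vector of annual totals, or the data frame from
#'   [annual_precipitation()].
#' @return List of class `pearson3_params` with `mean`, `cv`, `cs`, `n`.
#' @export
fit_pearson3 <- function(precip) {
  x <- if (is.data.frame(precip)) precip$precip_mm else as.numeric(precip)
  n <- length(x)
  if (n < 10) stop("need at least 10 years for a stable fit", call. = FALSE)
  if (length(unique(x)) < 3 || stats::sd(x) == 0)
    stop("degenerate sample: fewer than 3 distinct values", call. = FALSE)
  m <- mean(x)
  if (m <= 0) stop("mean precipitation must be positive", call. = FALSE)
  s <- stats::sd(x)
  g1 <- mean((x - m)^3) / (mean((x - m)^2))^1.5
  cs <- g1 * sqrt(n * (n - 1)) / (n - 2) # bias-corrected skew
  if (abs(cs) < 1e-6) cs <- sign(cs + (cs == 0)) * 1e-6
  structure(list(mean = m, cv = s / m, cs = cs, n = n),
            class = "pearson3_params")
}

#' @export
print.pearson3_params <- function(x, ...) {
  cat(sprintf("<pearson3_params> mean %.1f mm  cv %.3f  cs %.3f  (n = %d)\n",
              x$mean, x$cv, x$cs, x$n))
  invisible(x)
}

#' Design rainfall at an exceedance probability
#'
#' Pearson Type III quantile in the exceedance convention of hydrological
#' practice: `design_rainfall(params, p)` returns `x` with
#' `P(X >= x) = p`, so `p = 0.25` is the wet (high-flow) design value. The
#' distribution is the shifted gamma with shape `alpha = 4/cs^2`, scale
#' `mean * cv * |cs| / 2` and location `mean (1 - 2 cv / |cs|)` (mirrored
#' for negative skew); for `|cs| < 1e-4` it degenerates to the normal form
#' `mean (1 + cv z_(1-p))`.
#'
#' @param params A `pearson3_params` object (or list with mean, cv, cs).
#' @param p Exceedance probabilities in (0, 1), vectorised.
#' @return Design rainfall, mm.
#' @export
design_rainfall <- function(params, p) {
  stopifnot(all(p > 0 & p < 1))
  m <- params$mean; cv <- params$cv; cs <- params$cs
  if (abs(cs) < 1e-4)
    return(m * (1 + cv * stats::qnorm(1 - p)))
  alpha <- 4 / cs^2
  beta <- m * cv * abs(cs) / 2 # gamma scale
  if (cs > 0) {
    x0 <- m * (1 - 2 * cv / cs)
    x0 + stats::qgamma(1 - p, shape = alpha, scale = beta)
  } else {
    x0 <- m * (1 + 2 * cv / abs(cs))
    x0 - stats::qgamma(p, shape = alpha, scale = beta)
  }
}

#' Select typical hydrological years
#'
#' Ranks observed annual rainfall in descending order, fits a Pearson Type
#' III distribution by moments, computes the design rainfall at the four
#' conventional exceedance levels (25% high flow, 50% median water, 75% low
#' flow, 90% special dry), and picks for each level the observed year whose
#' total is nearest the design value, breaking ties toward the earlier
#' year.
#'
#' @param annual Data frame `year, precip_mm` (e.g. from
#'   [annual_precipitation()]).
#' @param p_levels Exceedance probabilities; default the four conventional
#'   levels.
#' @return Data frame of class `hydro_year_assignment` with columns
#'   `p, label, design_mm, year, precip_mm, empirical_p`; attribute
#'   `params` carries the fitted `pearson3_params`.
#' @export
select_typical_years <- function(annual,
                                 p_levels = c(0.25, 0.50, 0.75, 0.90)) {
  stopifnot(is.data.frame(annual), all(c("year", "precip_mm") %in% names(annual)))
  if (anyDuplicated(annual$year)) stop("duplicate years", call. = FALSE)
  if (any(annual$precip_mm < 0)) stop("negative annual totals", call. = FALSE)
  params <- fit_pearson3(annual$precip_mm)
  design <- design_rainfall(params, p_levels)
  n <- nrow(annual)
  ord <- order(-annual$precip_mm, annual$year)
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)
  labels <- hydro_year_labels(p_levels)
  pick <- function(target) {
    d <- abs(annual$precip_mm - target)
    cand <- which(d == min(d))
    cand[which.min(annual$year[cand])] # tie -> earlier year
  }
  idx <- vapply(design, pick, integer(1))
  out <- data.frame(
    p = p_levels, label = labels, design_mm = design,
    year = annual$year[idx], precip_mm = annual$precip_mm[idx],
    empirical_p = cumulative_frequency(rank_of[idx], n))
  structure(out, params = params,
            class = c("hydro_year_assignment", "data.frame"))
}

hydro_year_labels <- function(p) {
  std <- c(`0.25` = "high flow year", `0.5` = "median water year",
           `0.75` = "low flow year", `0.9` = "special dry year")
  lab <- std[as.character(p)]
  ifelse(is.na(lab), sprintf("p=%g year", p), lab)
}
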