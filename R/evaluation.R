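#' Aggregate a daily ET0 series to dekad or monthly scale
#'
#' Period totals (sums of daily ET0). Dekads follow the agrometeorological
#' convention: days 1-10, 11-20 and 21 to month end, so the third dekad has
#' 8-11 days. A period with incomplete daily coverage is flagged missing
#' (`NA`) rather than summed over fewer days.
#'
#' @param series A daily [et0_series()].
#' @param scale `"dekad"` or `"monthly"`.
#' @return An `et0_series` at the requested scale; dekad periods are
#'   labelled `"YYYY-MM-d1"`..`"d3"`, months `"YYYY-MM"`.
#' @export
aggregate_et0 <- function(series, scale = c("dekad", "monthly")) {
  scale <- match.arg(scale)
  stopifnot(inherits(series, "et0_series"), attr(series, "scale") == "daily")
  d <- as.Date(series$period)
  ym <- format(d, "%Y-%m")
  dom <- as.integer(format(d, "%d"))
  mlen <- days_in_month(d)
  if (scale == "monthly") {
    key <- ym
    expected <- tapply(mlen, key, max)
  } else {
    dk <- pmin((dom - 1L) %/% 10L + 1L, 3L)
    key <- paste0(ym, "-d", dk)
    expected <- tapply(ifelse(dk < 3L, 10L, mlen - 20L), key, max)
  }
  tot <- tapply(series$et0_mm, key, sum)
  cnt <- tapply(rep(1L, length(key)), key, sum)
  miss <- tapply(is.na(series$et0_mm), key, any)
  labs <- sort(unique(key))
  vals <- as.numeric(tot[labs])
  vals[cnt[labs] < expected[labs] | miss[labs]] <- NA_real_
  et0_series(labs, vals, model = attr(series, "model"), scale = scale)
}

days_in_month <- function(d) {
  first <- as.Date(format(d, "%Y-%m-01"))
  as.integer(format(seq_next_month(first) - 1, "%d"))
}

seq_next_month <- function(first) {
  y <- as.integer(format(first, "%Y")); m <- as.integer(format(first, "%m"))
  as.Date(sprintf("%d-%02d-01", y + (m == 12L), ifelse(m == 12L, 1L, m + 1L)))
}

#' Agreement statistics between a simulated and a standard ET0 series
#'
#' Computes the four statistics used for model evaluation, with the
#' simulated series `P` compared against the standard `Q`:
#' \itemize{
#'   \item `r2`: squared Pearson correlation of the pairs;
#'   \item `rmse`: `sqrt(mean((P - Q)^2))`, in mm per period;
#'   \item `mae`: `mean(|P - Q|)`, mm per period;
#'   \item `wi`: Willmott-style index of agreement
#'     `1 - sum((Q - P)^2) / sum((|Q - c| + |P - c|)^2)`.
#' }
#' Under `wi_convention = "paper"` (default) the centring constant `c` is
#' the mean of the simulated series `P`; `"willmott"` uses the conventional
#' observed mean `Q`. Periods missing in either series are dropped
#' pairwise. With zero variance in either series `r2` is undefined and
#' reported `NA`.
#'
#' @param simulated,standard `et0_series` objects at the same scale (or
#'   plain numeric vectors of equal length).
#' @param wi_convention Centring convention for the index of agreement.
#' @return One-row data frame `r2, rmse, mae, wi, n, p_value` (`p_value`
#'   from the correlation test, reported but never used for selection).
#' @export
agreement_metrics <- function(simulated, standard,
                              wi_convention = c("paper", "willmott")) {
  wi_convention <- match.arg(wi_convention)
  pq <- align_series(simulated, standard)
  P <- pq$P; Q <- pq$Q
  n <- length(P)
  if (n < 2) stop("need at least 2 aligned periods", call. = FALSE)
  centre <- if (wi_convention == "paper") mean(P) else mean(Q)
  wi <- 1 - sum((Q - P)^2) / sum((abs(Q - centre) + abs(P - centre))^2)
  degenerate <- stats::sd(P) == 0 || stats::sd(Q) == 0
  r2 <- if (degenerate) NA_real_ else stats::cor(P, Q)^2
  pval <- if (degenerate) NA_real_ else stats::cor.test(P, Q)$p.value
  data.frame(r2 = r2, rmse = sqrt(mean((P - Q)^2)), mae = mean(abs(P - Q)),
             wi = wi, n = n, p_value = pval)
}

align_series <- function(simulated, standard) {
  if (inherits(simulated, "et0_series") && inherits(standard, "et0_series")) {
    stopifnot(attr(simulated, "scale") == attr(standard, "scale"))
    common <- intersect(as.character(simulated$period),
                        as.character(standard$period))
    P <- simulated$et0_mm[match(common, as.character(simulated$period))]
    Q <- standard$et0_mm[match(common, as.character(standard$period))]
  } else {
    P <- as.numeric(if (is.data.frame(simulated)) simulated$et0_mm else simulated)
    Q <- as.numeric(if (is.data.frame(standard)) standard$et0_mm else standard)
    stopifnot(length(P) == length(Q))
  }
  ok <- !is.na(P) & !is.na(Q)
  list(P = P[ok], Q = Q[ok])
}

#' Model-comparison metric table
#'
#' For each requested year, model and scale, computes the agreement of the
#' simplified model against the Penman-Monteith standard calculated from
#' the same weather. This reproduces the shape of the typical-year
#' comparison tables: one row per (model, year, scale).
#'
#' @param weather A [weather_series()] covering the requested years.
#' @param years Integer calendar years to evaluate.
#' @param models Model labels among `"PT", "HA", "MC", "FR"` (the standard
#'   `"PM"` is always computed internally).
#' @param scales Subset of `c("daily", "dekad", "monthly")`.
#' @param params An [et0_params()].
#' @param wi_convention Passed to [agreement_metrics()].
#' @return Data frame `station, year, scale, model, r2, rmse, mae, wi, n`.
#' @export
comparison_table <- function(weather, years,
                             models = c("PT", "HA", "MC", "FR"),
                             scales = c("daily", "dekad", "monthly"),
                             params = et0_params(),
                             wi_convention = "paper") {
  stopifnot(inherits(weather, "weather_series"))
  st <- attr(weather, "station")
  scales <- match.arg(scales, c("daily", "dekad", "monthly"),
                      several.ok = TRUE)
  rows <- list()
  for (yr in years) {
    sub <- weather[as.integer(format(weather$date, "%Y")) == yr, ,
                   drop = FALSE]
    if (!nrow(sub))
      stop("no weather data for year ", yr, call. = FALSE)
    sub <- weather_series(as.data.frame(sub), st)
    pm_by_scale <- multi_scale(compute_et0(sub, "PM", params), scales)
    for (mod in models) {
      sim_by_scale <- multi_scale(compute_et0(sub, mod, params), scales)
      for (sc in scales) {
        met <- agreement_metrics(sim_by_scale[[sc]], pm_by_scale[[sc]],
                                 wi_convention)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(station = st$station_id, year = yr, scale = sc,
                           model = mod), met[c("r2", "rmse", "mae", "wi", "n")])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

multi_scale <- function(daily, scales) {
  out <- list()
  for (sc in scales)
    out[[sc]] <- if (sc == "daily") daily else aggregate_et0(daily, sc)
  out
}

#' Summarise the improvement between two metric tables
#'
#' Compares row-aligned before/after metric tables (same stations, years
#' and scale) for one metric, reporting both aggregation conventions in
#' use for such summaries:
#' \itemize{
#'   \item `mean_per_row_pct_change`: mean over rows of the per-row percent
#'     change;
#'   \item `pct_change_of_means`: percent change of the row means.
#' }
#' Signs follow the reporting convention: for the error metrics (`rmse`,
#' `mae`) a positive number is a reduction, `100 (before - after)/before`;
#' for `wi` (and `r2`) a positive number is an increase,
#' `100 (after - before)/before`.
#'
#' @param before,after Data frames containing at least `station`, `year`
#'   and the metric column; rows are matched on (station, year).
#' @param metric One of `"rmse"`, `"mae"`, `"wi"`, `"r2"`.
#' @param scale Optional label stored in the result (rows are filtered on a
#'   `scale` column when present).
#' @return List of class `improvement_summary`:
#'   `scale, metric, mean_per_row_pct_change, pct_change_of_means, n_rows`.
#' @export
summarize_improvement <- function(before, after,
                                  metric = c("rmse", "mae", "wi", "r2"),
                                  scale = NULL) {
  metric <- match.arg(metric)
  if (!is.null(scale) && "scale" %in% names(before)) {
    before <- before[before$scale == scale, , drop = FALSE]
    after <- after[after$scale == scale, , drop = FALSE]
  }
  key_b <- paste(before$station, before$year)
  key_a <- paste(after$station, after$year)
  if (nrow(before) != nrow(after) || !all(key_b %in% key_a))
    stop("before/after tables are not row-aligned on (station, year)",
         call. = FALSE)
  after <- after[match(key_b, key_a), , drop = FALSE]
  b <- before[[metric]]; a <- after[[metric]]
  if (!length(b)) stop("no rows to summarise", call. = FALSE)
  sgn <- if (metric %in% c("rmse", "mae")) 1 else -1
  structure(
    list(scale = if (is.null(scale)) NA_character_ else scale,
         metric = metric,
         mean_per_row_pct_change = mean(sgn * 100 * (b - a) / b),
         pct_change_of_means = sgn * 100 * (mean(b) - mean(a)) / mean(b),
         n_rows = length(b)),
    class = "improvement_summary")
}

#' @export
print.improvement_summary <- function(x, ...) {
  cat(sprintf(
    "<improvement_summary> %s (%s): per-row mean %+.2f%%, of-means %+.2f%% (n = %d)\n",
    x$metric, x$scale, x$mean_per_row_pct_change, x$pct_change_of_means,
    x$n_rows))
  invisible(x)
}

#' Published validation tables for the FAO-24 Radiation recalibration
#'
#' Long-format copies of the published per-station, per-year error analysis
#' of the original (`before`) and recalibrated (`after`) FAO-24 Radiation
#' model over the three Haihe Plain validation stations, at daily, monthly
#' and dekad scale. Shipped as plain CSV under `inst/extdata`; used to
#' reproduce the published improvement averages exactly.
#'
#' @return List of two data frames (`before`, `after`) with columns
#'   `station, year, scale, r2, rmse, mae, wi`.
#' @export
fr_validation_tables <- function() {
  rd <- function(f)
    utils::read.csv(system.file("extdata", f, package = "et0calib",
                                mustWork = TRUE))
  list(before = rd("fr_validation_before.csv"),
       after = rd("fr_validation_after.csv"))
}

#' Published daily model-comparison table
#'
#' Long-format copy of the published daily-scale comparison of the four
#' simplified models against the Penman-Monteith standard across the four
#' typical hydrological years and three stations (CSV under
#' `inst/extdata`).
#'
#' @return Data frame `station, year_type, model, r2, rmse, mae, wi`.
#' @export
model_comparison_daily <- function() {
  utils::read.csv(system.file("extdata", "model_comparison_daily.csv",
                              package = "et0calib", mustWork = TRUE))
}
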