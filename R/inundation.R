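#' Annual hydroperiod summary for a single plot
#'
#' Scans a regularly sampled water-level series for exceedances of a plot's
#' elevation and aggregates them to calendar-year flooding metrics. A sample
#' counts as inundated iff `level > elevation` (strict exceedance; ties
#' count dry, so results are reproducible bit-for-bit). Each sample
#' represents its own interval, so at 6-minute spacing every wet sample
#' contributes 0.1 h; no sub-interval crossing interpolation is applied.
#' Events are maximal consecutive runs of wet samples; missing samples
#' count as not inundated and break events; runs are also split at
#' calendar-year boundaries. Percent of year uses the full calendar-year
#' length (8760 h, or 8784 h in leap years) as denominator; data coverage
#' is reported separately and a warning is raised for years below
#' `min_coverage_warn`.
#'
#' @param series A [water_level_series()].
#' @param elevation Plot elevation, m, in `elevation_datum`.
#' @param plot_id Plot identifier carried into the output.
#' @param elevation_datum Datum of `elevation`; must match the series datum
#'   or the computation refuses to run.
#' @param min_coverage_warn Warn when a year's data coverage falls below
#'   this fraction (default 0.95); set to 0 to disable.
#' @return A tibble with one row per calendar year touched by the series:
#'   `plot_id`, `year`, `hours_inundated`, `percent_of_year`, `n_events`,
#'   `mean_event_duration` (NA when there are no events), `coverage`.
#'   Years with zero non-missing samples report coverage 0 and missing
#'   metrics.
#' @examples
#' wl <- water_level_series(rep(1, 10), "2015-06-01 00:00")
#' annual_inundation(wl, 0.5, "p1", min_coverage_warn = 0)
#' @export
annual_inundation <- function(series, elevation, plot_id = "plot",
                              elevation_datum = "NAVD88",
                              min_coverage_warn = 0.95) {
  stopifnot(inherits(series, "water_level_series"))
  if (length(elevation) != 1L || !is.finite(elevation)) {
    stop("elevation must be a single finite number")
  }
  if (!identical(series$datum, elevation_datum)) {
    stop("datum mismatch: series is in '", series$datum,
         "' but the elevation is in '", elevation_datum,
         "'; refusing to compute")
  }
  step_s <- series$interval * 60
  t0 <- series$start
  n <- length(series$levels)
  y1 <- as.integer(format(t0, "%Y", tz = "UTC"))
  y2 <- as.integer(format(wl_end_time(series), "%Y", tz = "UTC"))
  years <- y1:y2
  hours_inundated <- percent <- mean_dur <- coverage <- numeric(length(years))
  n_events <- integer(length(years))
  for (j in seq_along(years)) {
    y <- years[j]
    ys <- as.POSIXct(sprintf("%d-01-01", y), tz = "UTC")
    ye <- as.POSIXct(sprintf("%d-01-01", y + 1), tz = "UTC")
    k0 <- max(0, ceiling(as.numeric(difftime(ys, t0, units = "secs")) / step_s))
    k1 <- min(n - 1, ceiling(as.numeric(difftime(ye, t0, units = "secs")) / step_s) - 1)
    lev <- series$levels[(k0:k1) + 1L]
    year_hours <- as.numeric(difftime(ye, ys, units = "hours"))
    expected <- year_hours * 3600 / step_s
    n_ok <- sum(!is.na(lev))
    coverage[j] <- n_ok / expected
    if (n_ok == 0L) {
      hours_inundated[j] <- percent[j] <- mean_dur[j] <- NA_real_
      n_events[j] <- NA_integer_
      next
    }
    wet <- !is.na(lev) & lev > elevation
    hours_inundated[j] <- sum(wet) * step_s / 3600
    runs <- rle(wet)
    n_events[j] <- sum(runs$values)
    mean_dur[j] <- if (n_events[j] > 0) hours_inundated[j] / n_events[j] else NA_real_
    percent[j] <- 100 * hours_inundated[j] / year_hours
  }
  low <- which(!is.na(coverage) & coverage < min_coverage_warn & coverage > 0)
  if (min_coverage_warn > 0 && length(low)) {
    warning(sprintf("plot %s: data coverage below %.0f%% in year(s) %s",
                    plot_id, 100 * min_coverage_warn,
                    paste(years[low], collapse = ", ")))
  }
  tibble::tibble(plot_id = plot_id, year = years,
                 hours_inundated = hours_inundated,
                 percent_of_year = percent,
                 n_events = n_events,
                 mean_event_duration = mean_dur,
                 coverage = coverage)
}

#' Hydroperiod summaries for a whole plot table
#'
#' Applies [annual_inundation()] to every plot; plot elevations are static
#' across years (surveyed once and applied to the whole record, the
#' convention of long-term monitoring designs).
#'
#' @param series A [water_level_series()].
#' @param plots Plot table with `plot_id` and `elevation` (m NAVD88).
#' @inheritParams annual_inundation
#' @return A tibble of annual summaries keyed by (`plot_id`, `year`).
#' @export
inundation_table <- function(series, plots, elevation_datum = "NAVD88",
                             min_coverage_warn = 0.95) {
  stopifnot(is.data.frame(plots),
            all(c("plot_id", "elevation") %in% names(plots)))
  dplyr::bind_rows(lapply(seq_len(nrow(plots)), function(i) {
    annual_inundation(series, plots$elevation[i], plots$plot_id[i],
                      elevation_datum = elevation_datum,
                      min_coverage_warn = min_coverage_warn)
  }))
}

#' Mean Higher High Water from a water-level series
#'
#' Partitions the epoch into tidal days of 24.84 h starting at the epoch
#' start (partial trailing tidal days are dropped), takes each tidal day's
#' highest water (the higher of its up to two semidiurnal high waters), and
#' averages them.
#'
#' @param series A [water_level_series()].
#' @param epoch_start,epoch_end Epoch bounds (default: the full series);
#'   half-open `[start, end)`.
#' @param min_coverage Minimum fraction of non-missing samples in the epoch;
#'   below it the computation errors rather than return a biased datum.
#' @param tidal_day_hours Length of the tidal-day partition, hours.
#' @return MHHW in series datum units (m).
#' @export
compute_mhhw <- function(series, epoch_start = NULL, epoch_end = NULL,
                         min_coverage = 0.9, tidal_day_hours = 24.84) {
  stopifnot(inherits(series, "water_level_series"))
  epoch_start <- if (is.null(epoch_start)) series$start else as_wl_time(epoch_start)
  epoch_end <- if (is.null(epoch_end)) {
    wl_end_time(series) + series$interval * 60
  } else {
    as_wl_time(epoch_end)
  }
  t <- wl_timestamps(series)
  keep <- t >= epoch_start & t < epoch_end
  if (!any(keep)) stop("empty epoch: no samples in [epoch_start, epoch_end)")
  lev <- series$levels[keep]
  elapsed_h <- as.numeric(difftime(t[keep], epoch_start, units = "hours"))
  span_h <- as.numeric(difftime(epoch_end, epoch_start, units = "hours"))
  n_days <- floor(span_h / tidal_day_hours)
  if (n_days < 1) stop("epoch shorter than one tidal day (", tidal_day_hours, " h)")
  day <- floor(elapsed_h / tidal_day_hours)
  keep2 <- day < n_days
  lev <- lev[keep2]
  day <- day[keep2]
  cov <- mean(!is.na(lev))
  if (cov < min_coverage) {
    stop(sprintf("insufficient coverage for MHHW: %.1f%% present, >= %.0f%% required",
                 100 * cov, 100 * min_coverage))
  }
  ok <- !is.na(lev)
  daily_max <- tapply(lev[ok], day[ok], max)
  mean(daily_max)
}

#' Monthly mean sea level
#'
#' Arithmetic mean of non-missing samples in each calendar month; months
#' with no data inside the series span appear with a missing value so the
#' monthly grid stays complete.
#'
#' @param series A [water_level_series()].
#' @return A tibble with `year`, `month`, `msl` (m) and `n_obs`.
#' @export
monthly_mean_sea_level <- function(series) {
  stopifnot(inherits(series, "water_level_series"))
  lt <- as.POSIXlt(wl_timestamps(series), tz = "UTC")
  key <- (lt$year + 1900L) * 12L + lt$mon
  ok <- !is.na(series$levels)
  sums <- tapply(series$levels[ok], key[ok], sum)
  cnts <- tapply(series$levels[ok], key[ok], length)
  full <- seq(min(key), max(key))
  msl <- rep(NA_real_, length(full))
  n_obs <- rep(0L, length(full))
  idx <- match(as.integer(names(sums)), full)
  msl[idx] <- as.numeric(sums / cnts)
  n_obs[idx] <- as.integer(cnts)
  tibble::tibble(year = full %/% 12L, month = full %% 12L + 1L,
                 msl = msl, n_obs = n_obs)
}

#' Seasonally adjust a monthly series
#'
#' Removes the mean annual cycle: subtracts each calendar month's long-term
#' mean and restores the grand mean, so the adjusted series keeps the
#' original level and trend but loses the seasonal oscillation. Requires at
#' least 24 non-missing months.
#'
#' @param monthly A tibble with `year`, `month` and the value column.
#' @param value_col Name of the value column (default `"msl"`).
#' @return `monthly` with an added `<value_col>_adj` column.
#' @export
seasonally_adjust <- function(monthly, value_col = "msl") {
  stopifnot(is.data.frame(monthly),
            all(c("year", "month", value_col) %in% names(monthly)))
  v <- monthly[[value_col]]
  if (sum(!is.na(v)) < 24) {
    stop("seasonal adjustment needs at least 24 non-missing months")
  }
  clim <- tapply(v, monthly$month, mean, na.rm = TRUE)
  adj <- v - unname(clim[as.character(monthly$month)]) + mean(v, na.rm = TRUE)
  monthly[[paste0(value_col, "_adj")]] <- as.numeric(adj)
  monthly
}

#' Sea-level trend from a water-level series
#'
#' Convenience chain: monthly mean sea level, seasonal adjustment, then an
#' ordinary least-squares trend of the adjusted monthly means with calendar
#' year as the continuous predictor (see [fit_linear_trend()]). Year, not
#' decimal date, is the predictor because the seasonal adjustment absorbs
#' the within-year part of any trend into the climatology; regressing the
#' adjusted series on a within-year-varying axis would attenuate the slope
#' by var(year) / (var(year) + var(month)). Slope, intercept and standard
#' error are converted to millimetres.
#'
#' @param series A [water_level_series()].
#' @param alpha Significance level for the slope test.
#' @return A one-row trend-result tibble with slope in mm/yr.
#' @export
sea_level_trend <- function(series, alpha = 0.05) {
  m <- seasonally_adjust(monthly_mean_sea_level(series))
  tr <- fit_linear_trend(m$year, m$msl_adj,
                         alpha = alpha, variable = "msl",
                         plot_id = series$station)
  tr$slope <- tr$slope * 1000
  tr$intercept <- tr$intercept * 1000
  tr$slope_se <- tr$slope_se * 1000
  tr
}
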