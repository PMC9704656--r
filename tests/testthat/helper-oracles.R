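# Independent oracles and small fixture builders shared across tests.

# Sample-by-sample hydroperiod counter: a deliberately naive loop over the
# series, tracking wet runs per calendar year. Kept independent of the
# vectorised implementation it checks.
brute_force_inundation <- function(series, elevation, plot_id = "plot") {
  t <- wl_timestamps(series)
  yr <- as.integer(format(t, "%Y", tz = "UTC"))
  step_h <- series$interval / 60
  rows <- lapply(seq(min(yr), max(yr)), function(y) {
    lev <- series$levels[yr == y]
    ys <- as.POSIXct(sprintf("%d-01-01", y), tz = "UTC")
    ye <- as.POSIXct(sprintf("%d-01-01", y + 1), tz = "UTC")
    year_hours <- as.numeric(difftime(ye, ys, units = "hours"))
    n_ok <- 0L; n_wet <- 0L; events <- 0L; prev_wet <- FALSE
    for (x in lev) {
      if (is.na(x)) {
        prev_wet <- FALSE
        next
      }
      n_ok <- n_ok + 1L
      if (x > elevation) {
        n_wet <- n_wet + 1L
        if (!prev_wet) events <- events + 1L
        prev_wet <- TRUE
      } else {
        prev_wet <- FALSE
      }
    }
    hours <- n_wet * series$interval * 60 / 3600
    data.frame(
      plot_id = plot_id, year = y,
      hours_inundated = if (n_ok == 0L) NA_real_ else hours,
      percent_of_year = if (n_ok == 0L) NA_real_ else 100 * hours / year_hours,
      n_events = if (n_ok == 0L) NA_integer_ else events,
      mean_event_duration = if (n_ok == 0L || events == 0L) NA_real_
                            else hours / events,
      coverage = n_ok / (year_hours * 3600 / (series$interval * 60))
    )
  })
  do.call(rbind, rows)
}

# Closed-form OLS from the normal equations, written in the centred form
# slope = Sxy/Sxx (algebraically identical to (X'X)^-1 X'y but numerically
# stable for predictors far from zero, e.g. calendar years).
ols_oracle <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  df <- length(y) - 2L
  se <- sqrt(sum(resid^2) / df / sxx)
  tval <- slope / se
  list(intercept = intercept, slope = slope, slope_se = se,
       p_value = 2 * stats::pt(-abs(tval), df),
       r_squared = 1 - sum(resid^2) / sum((y - yb)^2))
}

# Random short water-level series with gaps, for property tests.
random_series <- function(n = NULL, na_frac = 0.05) {
  n <- n %||% sample(50:10000, 1)
  start <- as.POSIXct("2010-01-01", tz = "UTC") +
    sample(0:(5 * 365), 1) * 86400 + sample(0:239, 1) * 360
  lev <- cumsum(rnorm(n, 0, 0.05)) + 0.3 * sin(2 * pi * seq_len(n) / 124.2)
  lev[sample(n, ceiling(na_frac * n))] <- NA
  water_level_series(lev, start, interval = 6)
}

# Full-calendar-year series of a given constant or function of sample index.
full_year_series <- function(year, value) {
  ys <- as.POSIXct(sprintf("%d-01-01", year), tz = "UTC")
  ye <- as.POSIXct(sprintf("%d-01-01", year + 1), tz = "UTC")
  n <- as.numeric(difftime(ye, ys, units = "mins")) / 6
  lev <- if (is.function(value)) value(seq_len(n) - 1) else rep(value, n)
  water_level_series(lev, ys, interval = 6)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
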