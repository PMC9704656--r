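#' Water-level series container
#'
#' A regularly sampled water-level record referenced to a named vertical
#' datum. Samples sit on a fixed grid of `interval` minutes starting at
#' `start`; gaps are explicit `NA` values on the grid, never dropped rows,
#' so data-coverage accounting stays exact. Timestamps are treated as naive
#' local standard time on a monotone axis (stored as UTC internally, never
#' converted between zones).
#'
#' @param levels Numeric vector of water levels in metres relative to
#'   `datum`; `NA` marks a missing sample.
#' @param start `POSIXct` timestamp (or a `"YYYY-MM-DD HH:MM"` string) of the
#'   first sample.
#' @param interval Sampling interval in minutes; must divide 60.
#' @param datum Vertical datum label, e.g. `"NAVD88"`. Analyses refuse to mix
#'   datums.
#' @param station Free-text station label.
#'
#' @return An object of class `water_level_series`.
#' @seealso [simulate_water_levels()], [annual_inundation()]
#' @export
water_level_series <- function(levels, start, interval = 6, datum = "NAVD88",
                               station = "unknown") {
  start <- as_wl_time(start)
  levels <- as.numeric(levels)
  if (length(levels) < 1L) stop("a water_level_series needs at least one sample")
  if (length(interval) != 1L || !is.finite(interval) || interval <= 0 ||
      60 %% interval != 0) {
    stop("interval must be a positive number of minutes that divides 60")
  }
  if (any(is.infinite(levels))) stop("water levels must be finite or NA")
  structure(
    list(levels = levels, start = start, interval = as.numeric(interval),
         datum = as.character(datum), station = as.character(station)),
    class = "water_level_series"
  )
}

as_wl_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  out <- as.POSIXct(x, tz = "UTC")
  if (any(is.na(out))) stop("could not parse timestamp: ", x)
  out
}

#' @export
print.water_level_series <- function(x, ...) {
  cat(sprintf(
    "<water_level_series> %d samples @ %g min, datum %s, station %s\n  %s .. %s (%.1f%% present)\n",
    length(x$levels), x$interval, x$datum, x$station,
    format(x$start, "%Y-%m-%d %H:%M"),
    format(wl_end_time(x), "%Y-%m-%d %H:%M"),
    100 * mean(!is.na(x$levels))
  ))
  invisible(x)
}

#' @export
length.water_level_series <- function(x) length(x$levels)

wl_end_time <- function(series) {
  series$start + (length(series$levels) - 1) * series$interval * 60
}

#' Grid timestamps of a water-level series
#'
#' @param series A [water_level_series()].
#' @return A `POSIXct` vector, one element per sample.
#' @export
wl_timestamps <- function(series) {
  series$start + (seq_along(series$levels) - 1) * series$interval * 60
}

#' @export
as.data.frame.water_level_series <- function(x, ...) {
  data.frame(datetime = wl_timestamps(x), level = x$levels)
}

#' Configuration for the synthetic tide generator
#'
#' Describes a harmonic tide plus a linear sea-level-rise trend, an annual
#' cycle of mean level, and Gaussian sample noise. Defaults emulate a
#' semidiurnal US south-east Atlantic gauge over 2009--2019: one dominant
#' M2-like constituent (amplitude 0.69 m, period 12.42 h), a 13.2 mm/yr rise
#' in mean level, a 0.10 m annual cycle peaking in early autumn, and 0.12 m
#' residual (meteorological) noise at 6-minute spacing.
#'
#' The trend and seasonal terms use elapsed time in Julian years (365.25 d),
#' so a configured trend of `r` mm/yr raises the level by exactly `r` mm
#' 365.25 days after `start`.
#'
#' @param mean_level Mean water level at `start`, m relative to `datum`.
#' @param constituents List of named numeric vectors with elements
#'   `amplitude` (m, >= 0), `period` (hours, > 0) and `phase` (radians).
#' @param slr_trend Linear trend in mean level, mm/yr.
#' @param seasonal_amplitude Amplitude of the annual cycle of mean level, m.
#' @param seasonal_phase Phase of the annual cycle, radians (0 = sine zero
#'   crossing at `start` of year axis).
#' @param noise_sd Standard deviation of iid Gaussian sample noise, m.
#' @param start,end Half-open simulation window `[start, end)`; samples are
#'   generated at `start`, `start + interval`, ... strictly before `end`.
#' @param interval Sampling interval, minutes; must divide 60.
#' @param datum,station Labels recorded on the generated series.
#' @param seed Integer seed; identical seeds give bit-identical series.
#'
#' @return A list of class `tide_config`.
#' @export
tide_config <- function(mean_level = 0,
                        constituents = list(
                          m2 = c(amplitude = 0.69, period = 12.42, phase = 0)
                        ),
                        slr_trend = 13.2,
                        seasonal_amplitude = 0.10,
                        seasonal_phase = -2.95,
                        noise_sd = 0.12,
                        start = "2009-01-01 00:00",
                        end = "2020-01-01 00:00",
                        interval = 6,
                        datum = "NAVD88",
                        station = "synthetic",
                        seed = 1L) {
  start <- as_wl_time(start)
  end <- as_wl_time(end)
  if (!(end > start)) stop("tide_config: end must be after start")
  if (60 %% interval != 0) stop("tide_config: interval must divide 60 minutes")
  if (noise_sd < 0) stop("tide_config: noise_sd must be >= 0")
  if (seasonal_amplitude < 0) stop("tide_config: seasonal_amplitude must be >= 0")
  constituents <- lapply(constituents, function(k) {
    k <- unlist(k)
    need <- c("amplitude", "period", "phase")
    if (!all(need %in% names(k))) {
      stop("each constituent needs amplitude, period and phase")
    }
    if (k[["amplitude"]] < 0) stop("constituent amplitudes must be >= 0")
    if (k[["period"]] <= 0) stop("constituent periods must be > 0")
    k[need]
  })
  structure(
    list(mean_level = mean_level, constituents = constituents,
         slr_trend = slr_trend, seasonal_amplitude = seasonal_amplitude,
         seasonal_phase = seasonal_phase, noise_sd = noise_sd,
         start = start, end = end, interval = interval,
         datum = datum, station = station, seed = as.integer(seed)),
    class = "tide_config"
  )
}

#' Simulate a water-level series
#'
#' Generates a regularly sampled water-level record as the sum of a mean
#' level, a linear sea-level-rise trend, an annual sinusoid, harmonic tidal
#' constituents and iid Gaussian noise:
#' \deqn{h(t) = \bar h + \beta t + A_s \sin(2\pi t + \phi_s) +
#'   \sum_i a_i \sin(2\pi \tau / T_i + \phi_i) + \epsilon}
#' with \eqn{t} in Julian years and \eqn{\tau} in hours since `start`.
#'
#' @param config A [tide_config()].
#' @return A [water_level_series()].
#' @examples
#' wl <- simulate_water_levels(tide_config(end = "2009-02-01 00:00"))
#' wl
#' @export
simulate_water_levels <- function(config = tide_config()) {
  stopifnot(inherits(config, "tide_config"))
  step_s <- config$interval * 60
  n <- floor(as.numeric(difftime(config$end, config$start, units = "secs")) / step_s)
  if (n < 1) stop("simulation window shorter than one sampling interval")
  hours <- (seq_len(n) - 1) * config$interval / 60
  yrs <- hours / 8766  # 365.25-day Julian years
  level <- rep(config$mean_level, n) + (config$slr_trend / 1000) * yrs
  if (config$seasonal_amplitude > 0) {
    level <- level +
      config$seasonal_amplitude * sin(2 * pi * yrs + config$seasonal_phase)
  }
  for (k in config$constituents) {
    if (k[["amplitude"]] > 0) {
      level <- level +
        k[["amplitude"]] * sin(2 * pi * hours / k[["period"]] + k[["phase"]])
    }
  }
  if (config$noise_sd > 0) {
    level <- level + withr::with_seed(config$seed, rnorm(n, 0, config$noise_sd))
  }
  water_level_series(level, config$start, config$interval,
                     datum = config$datum, station = config$station)
}
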