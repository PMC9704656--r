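#' Describe one marsh segment for the transect generator
#'
#' A segment is a set of parallel transects running from the forest edge
#' (high elevation) down to the creek bank (low elevation). Zones are
#' assigned from elevation against fixed boundaries: `zone_breaks` are the
#' ascending boundary elevations and `zone_labels` the zone names from the
#' lowest band upward (one more label than breaks).
#'
#' @param transects Number of parallel transects.
#' @param plots_per_transect Plots per transect; monitoring designs here use
#'   8 or 9.
#' @param elev_top Elevation at the forest edge, m NAVD88.
#' @param elev_bottom Elevation at the creek bank, m NAVD88.
#' @param lengths_m Transect lengths in metres (recycled across transects).
#' @param zone_breaks Ascending elevation boundaries between zones, m NAVD88;
#'   must lie strictly inside `(elev_bottom, elev_top)`.
#' @param zone_labels Zone names from lowest to highest band.
#'
#' @return A list of class `marsh_segment`.
#' @export
marsh_segment <- function(transects = 3, plots_per_transect = 9,
                          elev_top = 1.09, elev_bottom = -0.467,
                          lengths_m = c(244, 258, 273),
                          zone_breaks = c(0.45, 0.75),
                          zone_labels = c("low", "mid", "high")) {
  if (!plots_per_transect %in% c(8L, 9L)) {
    stop("plots_per_transect must be 8 or 9")
  }
  if (elev_top <= elev_bottom) stop("elev_top must exceed elev_bottom")
  zone_breaks <- sort(as.numeric(zone_breaks))
  if (any(zone_breaks <= elev_bottom) || any(zone_breaks >= elev_top)) {
    stop("zone boundaries outside the segment elevation range")
  }
  if (length(zone_labels) != length(zone_breaks) + 1L) {
    stop("need one more zone label than zone boundaries")
  }
  if (!all(zone_labels %in% c("high", "mid", "low"))) {
    stop("zone labels must come from {high, mid, low}")
  }
  structure(
    list(transects = as.integer(transects),
         plots_per_transect = as.integer(plots_per_transect),
         elev_top = elev_top, elev_bottom = elev_bottom,
         lengths_m = rep_len(as.numeric(lengths_m), transects),
         zone_breaks = zone_breaks, zone_labels = zone_labels),
    class = "marsh_segment"
  )
}

#' Configuration for the synthetic marsh-transect generator
#'
#' Defaults emulate a 51-plot monitoring design: Segment A with three
#' transects of nine plots spanning 1.09 down to -0.467 m NAVD88 with low,
#' mid and high zones, and Segment B with three transects of eight plots
#' spanning 1.117 down to -0.255 m with only low and high zones (no
#' mid-marsh mixed-species band). Plot elevations descend linearly from
#' forest to creek with small Gaussian survey jitter (default sd 0.01 m,
#' RTK-grade vertical noise), clamped to the segment range.
#'
#' @param segments Named list of [marsh_segment()] objects.
#' @param elev_jitter_sd Standard deviation of elevation jitter, m.
#' @param seed Integer seed for the jitter.
#'
#' @return A list of class `marsh_config`.
#' @export
marsh_config <- function(segments = list(
                           A = marsh_segment(),
                           B = marsh_segment(
                             plots_per_transect = 8,
                             elev_top = 1.117, elev_bottom = -0.255,
                             lengths_m = c(93, 98, 104),
                             zone_breaks = 0.75,
                             zone_labels = c("low", "high")
                           )
                         ),
                         elev_jitter_sd = 0.01,
                         seed = 1L) {
  if (is.null(names(segments)) || any(!nzchar(names(segments)))) {
    stop("segments must be a named list")
  }
  lapply(segments, function(s) {
    if (!inherits(s, "marsh_segment")) stop("each segment must be a marsh_segment")
  })
  if (elev_jitter_sd < 0) stop("elev_jitter_sd must be >= 0")
  structure(
    list(segments = segments, elev_jitter_sd = elev_jitter_sd,
         seed = as.integer(seed)),
    class = "marsh_config"
  )
}

zone_vegetation <- c(low = "Spartina alterniflora",
                     mid = "mixed meadow",
                     high = "Juncus roemerianus")

#' Simulate a marsh plot table
#'
#' Lays plots out along each transect at equal spacing from the forest edge
#' to the creek bank, draws elevations as a linear descent plus jitter
#' (clamped to the segment range), and assigns each plot a zone from its
#' elevation against the segment's fixed zone boundaries.
#'
#' @param config A [marsh_config()].
#' @return A tibble with one row per plot: `plot_id`, `segment`, `transect`,
#'   `position_index` (1 = forest edge), `distance_from_forest` (m),
#'   `elevation` (m NAVD88), `zone`, `vegetation`.
#' @examples
#' plots <- simulate_marsh(marsh_config())
#' nrow(plots)  # 51
#' @export
simulate_marsh <- function(config = marsh_config()) {
  stopifnot(inherits(config, "marsh_config"))
  rows <- withr::with_seed(config$seed, {
    out <- list()
    for (seg_name in names(config$segments)) {
      s <- config$segments[[seg_name]]
      for (tr in seq_len(s$transects)) {
        p <- s$plots_per_transect
        base <- seq(s$elev_top, s$elev_bottom, length.out = p)
        elev <- base
        if (config$elev_jitter_sd > 0) {
          elev <- elev + rnorm(p, 0, config$elev_jitter_sd)
        }
        elev <- pmin(pmax(elev, s$elev_bottom), s$elev_top)
        zone <- as.character(cut(elev, c(-Inf, s$zone_breaks, Inf),
                                 labels = s$zone_labels))
        out[[length(out) + 1L]] <- tibble::tibble(
          plot_id = sprintf("%s-T%d-P%d", seg_name, tr, seq_len(p)),
          segment = seg_name,
          transect = tr,
          position_index = seq_len(p),
          distance_from_forest = (seq_len(p) - 1) / (p - 1) * s$lengths_m[tr],
          elevation = elev,
          zone = zone,
          vegetation = unname(zone_vegetation[zone])
        )
      }
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Map plot elevations to design inundation rates of change
#'
#' The porewater generator couples each plot's nutrient trend to that plot's
#' rate of change in annual inundation hours. This helper supplies the
#' design rates: a linear decrease with elevation over the monitored
#' elevation span, from `rate_range[2]` h/yr per yr at the lowest creekbank
#' elevation to `rate_range[1]` at the highest forest-edge elevation
#' (clamped at both ends). The defaults reproduce the observed span of
#' significant inundation trends in south-east Atlantic monitoring
#' transects, about 7.25--129.33 h/yr per yr.
#'
#' @param plots Plot table from [simulate_marsh()] or [read_plot_table()].
#' @param rate_range Rates at the (highest, lowest) monitored elevations,
#'   h/yr per yr.
#' @param elev_range Elevation span (m NAVD88) over which rates interpolate.
#' @return A named numeric vector of rates keyed by `plot_id`.
#' @export
default_inundation_rates <- function(plots,
                                     rate_range = c(7.25, 129.33),
                                     elev_range = c(-0.467, 1.117)) {
  stopifnot(is.data.frame(plots), all(c("plot_id", "elevation") %in% names(plots)))
  rel <- (plots$elevation - elev_range[1]) / diff(elev_range)
  r <- rate_range[2] - (rate_range[2] - rate_range[1]) * rel
  r <- pmin(pmax(r, min(rate_range)), max(rate_range))
  stats::setNames(r, plots$plot_id)
}

#' Mean design inundation rate over low-marsh plots of the nominal layout
#'
#' The jitter-free default layout fixes the expected mean low-marsh
#' inundation rate of change; porewater nutrient couplings are calibrated
#' against it so that the generator's mean low-marsh nutrient trend equals a
#' chosen target rate.
#'
#' @param config A [marsh_config()]; its jitter is forced to zero.
#' @return Mean of [default_inundation_rates()] over low-zone plots,
#'   h/yr per yr.
#' @export
nominal_low_marsh_rate <- function(config = marsh_config()) {
  config$elev_jitter_sd <- 0
  plots <- simulate_marsh(config)
  rates <- default_inundation_rates(plots)
  mean(rates[plots$plot_id[plots$zone == "low"]])
}
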