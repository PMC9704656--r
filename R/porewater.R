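#' Configuration for the synthetic porewater generator
#'
#' Generates replicate porewater chemistry (NH4, PO4, salinity) for every
#' plot, growing-season month and year. Each concentration is a zone
#' baseline plus a linear trend coupled to the plot's inundation rate of
#' change, a fixed month effect, and Gaussian noise, truncated below at the
#' analytical detection floor:
#' \deqn{c = b_{zone} + \gamma \, r \, (year - year_0) + m_{month} + \epsilon}
#' where \eqn{r} is the plot's inundation rate of change (h/yr per yr) and
#' \eqn{\gamma} the coupling (uM/yr per h/yr/yr). Salinity is analogous with
#' a common (negative) linear trend instead of the coupling.
#'
#' The default couplings are calibrated so that the *mean* low-marsh nutrient
#' trend of the default layout equals the target mean rates
#' (`nh4_low_rate` = 8.96 and `po4_low_rate` = 0.86 uM/yr):
#' `coupling = target / nominal_low_marsh_rate()`.
#'
#' @param baseline Named list of per-zone baseline levels (named numeric
#'   vectors over zones) for `nh4`, `po4` (uM) and `salinity` (psu); all > 0.
#' @param coupling_nh4,coupling_po4 Nutrient trend per unit inundation rate
#'   of change, uM/yr per (h/yr per yr). `NULL` (default) calibrates from
#'   `nh4_low_rate` / `po4_low_rate`.
#' @param nh4_low_rate,po4_low_rate Target mean low-marsh trends, uM/yr,
#'   used only when the corresponding coupling is `NULL`.
#' @param salinity_trend Common salinity trend, psu/yr (negative for a
#'   freshening marsh).
#' @param month_effects Named list of per-month additive effects (one value
#'   per element of `months`) for each variable; each should sum to zero so
#'   the seasonal cycle does not bias annual trends.
#' @param noise_sd Named list of per-zone Gaussian noise standard deviations
#'   for each variable.
#' @param detection_floor Lower truncation for nutrient concentrations, uM.
#' @param n_replicates Replicate samples per plot-month (>= 1).
#' @param months Sampled months (growing season, May--August by default).
#' @param years Sampled years.
#' @param seed Integer seed.
#'
#' @return A list of class `porewater_config` with resolved couplings.
#' @export
porewater_config <- function(baseline = list(
                               nh4 = c(high = 10, mid = 20, low = 55),
                               po4 = c(high = 1.5, mid = 3, low = 5),
                               salinity = c(high = 34, mid = 32, low = 30)
                             ),
                             coupling_nh4 = NULL,
                             coupling_po4 = NULL,
                             nh4_low_rate = 8.96,
                             po4_low_rate = 0.86,
                             salinity_trend = -1.2,
                             month_effects = list(
                               nh4 = c(-6, -2, 2, 6),
                               po4 = c(-0.4, -0.1, 0.1, 0.4),
                               salinity = c(-1, 0, 0, 1)
                             ),
                             noise_sd = list(
                               nh4 = c(high = 5, mid = 10, low = 25),
                               po4 = c(high = 0.5, mid = 1, low = 2),
                               salinity = c(high = 3, mid = 3, low = 3)
                             ),
                             detection_floor = 0.01,
                             n_replicates = 3L,
                             months = 5:8,
                             years = 2009:2019,
                             seed = 1L) {
  vars <- c("nh4", "po4", "salinity")
  if (!all(vars %in% names(baseline))) stop("baseline needs nh4, po4 and salinity")
  for (v in vars) {
    if (any(baseline[[v]] <= 0)) stop("baselines must be > 0 (", v, ")")
    if (any(noise_sd[[v]] < 0)) stop("noise_sd must be >= 0 (", v, ")")
    if (length(month_effects[[v]]) != length(months)) {
      stop("month_effects$", v, " needs one value per sampled month")
    }
  }
  if (detection_floor < 0) stop("detection_floor must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (length(years) < 2) stop("need at least two sampled years")
  if (is.null(coupling_nh4) || is.null(coupling_po4)) {
    r_low <- nominal_low_marsh_rate()
    if (is.null(coupling_nh4)) coupling_nh4 <- nh4_low_rate / r_low
    if (is.null(coupling_po4)) coupling_po4 <- po4_low_rate / r_low
  }
  structure(
    list(baseline = baseline,
         coupling_nh4 = coupling_nh4, coupling_po4 = coupling_po4,
         nh4_low_rate = nh4_low_rate, po4_low_rate = po4_low_rate,
         salinity_trend = salinity_trend,
         month_effects = lapply(month_effects, unname),
         noise_sd = noise_sd,
         detection_floor = detection_floor,
         n_replicates = as.integer(n_replicates),
         months = as.integer(months), years = as.integer(years),
         seed = as.integer(seed)),
    class = "porewater_config"
  )
}

#' Simulate a long-format porewater sample table
#'
#' Draws `n_replicates` samples for every plot, year and growing-season
#' month. NH4 and PO4 trends are coupled to each plot's inundation rate of
#' change (see [porewater_config()]); salinity declines linearly. Nutrient
#' concentrations are truncated below at the detection floor and salinity
#' at zero.
#'
#' @param plots Plot table from [simulate_marsh()] or [read_plot_table()].
#' @param inundation_rates Named numeric vector of inundation rates of
#'   change (h/yr per yr) keyed by `plot_id`; every plot must be present.
#'   See [default_inundation_rates()].
#' @param config A [porewater_config()].
#' @return A tibble with columns `plot_id`, `year`, `month`, `replicate`,
#'   `nh4` (uM), `po4` (uM), `salinity` (psu).
#' @examples
#' plots <- simulate_marsh(marsh_config())
#' pw <- simulate_porewater(plots, default_inundation_rates(plots))
#' @export
simulate_porewater <- function(plots, inundation_rates,
                               config = porewater_config()) {
  stopifnot(is.data.frame(plots), inherits(config, "porewater_config"))
  missing_rate <- setdiff(plots$plot_id, names(inundation_rates))
  if (length(missing_rate)) {
    stop("missing inundation rate for plot(s): ",
         paste(missing_rate, collapse = ", "))
  }
  bad_zone <- setdiff(unique(plots$zone), names(config$baseline$nh4))
  if (length(bad_zone)) {
    stop("no baseline configured for zone(s): ", paste(bad_zone, collapse = ", "))
  }
  g <- expand.grid(replicate = seq_len(config$n_replicates),
                   month = config$months,
                   year = config$years,
                   plot_id = plots$plot_id,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[order(g$plot_id, g$year, g$month, g$replicate), ]
  zone <- plots$zone[match(g$plot_id, plots$plot_id)]
  rate <- unname(inundation_rates[g$plot_id])
  dt <- g$year - min(config$years)
  mi <- match(g$month, config$months)
  n <- nrow(g)
  noise <- withr::with_seed(config$seed, list(
    nh4 = rnorm(n, 0, config$noise_sd$nh4[zone]),
    po4 = rnorm(n, 0, config$noise_sd$po4[zone]),
    salinity = rnorm(n, 0, config$noise_sd$salinity[zone])
  ))
  conc <- function(var, coupling) {
    pmax(config$detection_floor,
         unname(config$baseline[[var]][zone]) + coupling * rate * dt +
           config$month_effects[[var]][mi] + noise[[var]])
  }
  tibble::tibble(
    plot_id = g$plot_id,
    year = as.integer(g$year),
    month = as.integer(g$month),
    replicate = as.integer(g$replicate),
    nh4 = conc("nh4", config$coupling_nh4),
    po4 = conc("po4", config$coupling_po4),
    salinity = pmax(0, unname(config$baseline$salinity[zone]) +
                      config$salinity_trend * dt +
                      config$month_effects$salinity[mi] + noise$salinity)
  )
}
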