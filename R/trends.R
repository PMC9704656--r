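#' Average replicate porewater samples to monthly plot means
#'
#' Arithmetic mean of the available replicates for each plot, year and
#' month; a variable's mean is missing when all its replicates are missing,
#' and plot-months with no rows at all are simply absent.
#'
#' @param samples Porewater sample table (see [simulate_porewater()] /
#'   [read_porewater_table()]).
#' @return A tibble with `plot_id`, `year`, `month`, `nh4`, `po4`,
#'   `salinity` and `n_replicates`.
#' @export
monthly_plot_means <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("plot_id", "year", "month") %in% names(samples)))
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  samples |>
    dplyr::group_by(.data$plot_id, .data$year, .data$month) |>
    dplyr::summarise(nh4 = mean_or_na(.data$nh4),
                     po4 = mean_or_na(.data$po4),
                     salinity = mean_or_na(.data$salinity),
                     n_replicates = dplyr::n(),
                     .groups = "drop")
}

#' Ordinary least-squares linear trend with slope test
#'
#' Fits `y = a + b x` by OLS (the predictor is centred internally for
#' numerical stability; the slope is invariant to centring), with a
#' two-sided t test on the slope at level `alpha`. When the response is
#' constant (zero total sum of squares) the slope is 0, the R-squared is
#' reported as 0 and the p-value as missing.
#'
#' @param x Numeric predictor (typically calendar year).
#' @param y Numeric response; pairs with missing values are dropped.
#' @param alpha Significance level for the `significant` flag.
#' @param variable,plot_id Labels carried into the result.
#' @return A one-row tibble: `plot_id`, `variable`, `slope`, `intercept`,
#'   `slope_se`, `t_stat`, `p_value`, `r_squared`, `n`, `significant`.
#' @examples
#' fit_linear_trend(2009:2019, 2 * (2009:2019) + 1)
#' @export
fit_linear_trend <- function(x, y, alpha = 0.05, variable = NA_character_,
                             plot_id = NA_character_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("fit_linear_trend() needs >= 3 non-missing (x, y) pairs, got ", n)
  if (max(x) == min(x)) stop("fit_linear_trend(): degenerate predictor (all x equal)")
  xm <- mean(x)
  fit <- lm(y ~ I(x - xm))
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L]) - slope * xm
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) {
    slope <- 0          # exact convention for a constant response
    intercept <- mean(y)
    slope_se <- 0
    t_stat <- NA_real_
    p <- NA_real_
    r2 <- 0
  } else {
    # noise-free inputs are legitimate here; muffle summary.lm's
    # "essentially perfect fit" warning for that case only
    sm <- withCallingHandlers(summary(fit), warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
    slope_se <- sm$coefficients[2L, 2L]
    t_stat <- sm$coefficients[2L, 3L]
    p <- sm$coefficients[2L, 4L]
    r2 <- sm$r.squared
  }
  tibble::tibble(plot_id = plot_id, variable = variable, slope = slope,
                 intercept = intercept, slope_se = slope_se, t_stat = t_stat,
                 p_value = p, r_squared = r2, n = n,
                 significant = !is.na(p) && p < alpha)
}

#' Plot-level porewater trends (monthly means as within-year replicates)
#'
#' Regresses a plot's monthly mean concentrations against calendar year,
#' treating the growing-season monthly means as replicates within each year
#' (n = 44 for a complete 11-year, 4-month record).
#'
#' @param monthly_means Output of [monthly_plot_means()].
#' @param variable One of `"nh4"`, `"po4"`, `"salinity"`.
#' @param alpha Significance level.
#' @return A tibble of trend results, one row per plot.
#' @export
porewater_plot_trends <- function(monthly_means,
                                  variable = c("nh4", "po4", "salinity"),
                                  alpha = 0.05) {
  variable <- match.arg(variable)
  parts <- split(monthly_means, monthly_means$plot_id)
  dplyr::bind_rows(lapply(parts, function(d) {
    fit_linear_trend(d$year, d[[variable]], alpha = alpha,
                     variable = variable, plot_id = d$plot_id[1])
  }))
}

#' Plot-level inundation trends (annual totals)
#'
#' Regresses each plot's annual hours inundated against calendar year
#' (n = 11 for an 11-year record). Years with missing metrics (zero
#' coverage) are dropped.
#'
#' @param inundation Output of [inundation_table()].
#' @param alpha Significance level.
#' @return A tibble of trend results, one row per plot, with
#'   `variable = "inundation_hours"` and slopes in h/yr per yr.
#' @export
inundation_plot_trends <- function(inundation, alpha = 0.05) {
  parts <- split(inundation, inundation$plot_id)
  dplyr::bind_rows(lapply(parts, function(d) {
    fit_linear_trend(d$year, d$hours_inundated, alpha = alpha,
                     variable = "inundation_hours", plot_id = d$plot_id[1])
  }))
}

#' Arrange plot trends as a transect-ordered rate grid
#'
#' Orders one trend result per plot by segment, transect and position from
#' the forest edge, and flags cells whose trend is non-significant at
#' `alpha` as masked. Masking never changes a slope, only its visibility:
#' the `slope` column always carries the estimate, `masked` says whether a
#' rate-grid display would blank the cell, and `mask_reason` records why.
#'
#' @param trends Trend-result tibble with one row per plot.
#' @param plots Plot table supplying the layout.
#' @param alpha Significance level used for masking.
#' @return A tibble ordered by (`segment`, `transect`, `position_index`).
#' @export
rate_grid <- function(trends, plots, alpha = 0.05) {
  stopifnot(is.data.frame(trends), is.data.frame(plots))
  missing_tr <- setdiff(plots$plot_id, trends$plot_id)
  if (length(missing_tr)) {
    stop("no trend result for plot(s): ", paste(missing_tr, collapse = ", "))
  }
  g <- dplyr::inner_join(
    plots[, c("plot_id", "segment", "transect", "position_index", "elevation")],
    trends[, c("plot_id", "variable", "slope", "p_value", "n")],
    by = "plot_id"
  )
  g$masked <- is.na(g$p_value) | g$p_value >= alpha
  g$mask_reason <- ifelse(g$masked, sprintf("p >= %g", alpha), "")
  dplyr::arrange(g, .data$segment, .data$transect, .data$position_index)
}

#' Regress nutrient rates of change on inundation rates of change
#'
#' The cross-plot, slope-on-slope stage: ordinary least squares of
#' plot-level nutrient trend slopes (uM/yr) on plot-level inundation trend
#' slopes (h/yr per yr) across all plots, with no significance filtering of
#' either set of slopes.
#'
#' @param nutrient_trends,inundation_trends Trend tibbles with one row per
#'   plot; the two plot sets must match exactly.
#' @param alpha Significance level for the relation's slope test.
#' @return A one-row tibble: `variable`, `slope` ((uM/yr) per (h/yr/yr)),
#'   `intercept`, `slope_se`, `p_value`, `r_squared`, `n_plots`.
#' @export
rates_vs_inundation <- function(nutrient_trends, inundation_trends,
                                alpha = 0.05) {
  if (!setequal(nutrient_trends$plot_id, inundation_trends$plot_id) ||
      anyDuplicated(nutrient_trends$plot_id) ||
      anyDuplicated(inundation_trends$plot_id)) {
    stop("mismatched plot ids between nutrient and inundation trends")
  }
  m <- dplyr::inner_join(
    nutrient_trends[, c("plot_id", "variable", "slope")],
    inundation_trends[, c("plot_id", "slope")],
    by = "plot_id", suffix = c("_nutrient", "_inundation")
  )
  if (nrow(m) < 3) stop("need >= 3 matched plots, got ", nrow(m))
  tr <- fit_linear_trend(m$slope_inundation, m$slope_nutrient, alpha = alpha,
                         variable = m$variable[1])
  tibble::tibble(variable = m$variable[1], slope = tr$slope,
                 intercept = tr$intercept, slope_se = tr$slope_se,
                 p_value = tr$p_value, r_squared = tr$r_squared,
                 n_plots = nrow(m))
}

#' Monthly anomalies and their trend
#'
#' Anomaly of a monthly series from its long-term monthly climatology
#' (value minus that calendar month's mean over the record), plus an OLS
#' trend of the anomalies against decimal year. Requires at least 24
#' non-missing months.
#'
#' @param monthly A tibble with `year`, `month` and the value column.
#' @param value_col Name of the value column (default `"value"`).
#' @param alpha Significance level for the trend test.
#' @return A list with `anomalies` (the input plus an `anomaly` column) and
#'   `trend` (a one-row trend-result tibble).
#' @export
monthly_anomaly <- function(monthly, value_col = "value", alpha = 0.05) {
  stopifnot(is.data.frame(monthly),
            all(c("year", "month", value_col) %in% names(monthly)))
  v <- monthly[[value_col]]
  if (sum(!is.na(v)) < 24) stop("monthly_anomaly() needs at least 24 non-missing months")
  clim <- tapply(v, monthly$month, mean, na.rm = TRUE)
  monthly$anomaly <- as.numeric(v - unname(clim[as.character(monthly$month)]))
  trend <- fit_linear_trend(decimal_year(monthly$year, monthly$month),
                            monthly$anomaly, alpha = alpha,
                            variable = paste0(value_col, "_anomaly"))
  list(anomalies = monthly, trend = trend)
}
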