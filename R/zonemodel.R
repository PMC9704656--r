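#' Nakagawa marginal and conditional R-squared
#'
#' Variance-explained decomposition for a linear mixed model with additive
#' variance components: marginal R2 is the share of total variance
#' attributable to the fixed effects, conditional R2 the share attributable
#' to fixed plus random effects,
#' \deqn{R^2_m = \sigma^2_f / (\sigma^2_f + \sum \sigma^2_r + \sigma^2_e),
#'       \quad
#'       R^2_c = (\sigma^2_f + \sum \sigma^2_r) / (\sigma^2_f + \sum \sigma^2_r + \sigma^2_e)}
#' Negative component estimates are truncated at zero before the ratio is
#' formed, so conditional R2 is never below marginal R2.
#'
#' @param var_fixed Variance of the fixed-effects predictions.
#' @param var_random Numeric vector of random-intercept variances.
#' @param var_resid Residual variance.
#' @return A list with `marginal` and `conditional`.
#' @examples
#' nakagawa_r2(2, 1, 1)  # marginal 0.5, conditional 0.75
#' @export
nakagawa_r2 <- function(var_fixed, var_random, var_resid) {
  var_fixed <- max(0, var_fixed)
  var_random <- pmax(0, var_random)
  var_resid <- max(0, var_resid)
  den <- var_fixed + sum(var_random) + var_resid
  if (den <= 0) return(list(marginal = 0, conditional = 0))
  list(marginal = var_fixed / den,
       conditional = (var_fixed + sum(var_random)) / den)
}

#' Zone-by-year linear mixed-effects model for porewater concentrations
#'
#' Compares log concentrations between marsh zones and between the first
#' and final monitoring years within one marsh segment. The response is the
#' natural log of the plot-level monthly mean concentration; fixed effects
#' are zone, year and their interaction; a single random intercept is
#' fitted for month nested within year, i.e. one intercept per year-month
#' cell (REML). With only two years, a separate year random intercept would
#' be confounded with the fixed year effect, and the nested cell intercept
#' is what places the year test at the month-within-year stratum (for a
#' complete 4-month, 2-year design: denominator DF 8 - 2 = 6) under the
#' containment method. The ANOVA table uses sequential (Type-I) F tests
#' with containment denominator degrees of freedom. Marginal and
#' conditional R2 follow [nakagawa_r2()], with the fixed-effects variance
#' taken as the variance of the population-level predictions.
#'
#' Zero or negative concentrations are a hard error (no silent offset is
#' added before the log); the offending plot-months are listed.
#'
#' @param monthly_means Output of [monthly_plot_means()].
#' @param plots Plot table supplying `segment` and `zone`.
#' @param segment Segment to model.
#' @param variable `"nh4"` or `"po4"`.
#' @param years The two years compared (default first and last present).
#' @param alpha Significance level used when printing.
#' @return An object of class `zone_model`: a list with `segment`,
#'   `variable`, `years`, `anova` (term, num_df, den_df, f_value, p_value),
#'   `variance_components` (fixed, year, month_in_year, residual),
#'   `marginal_r2`, `conditional_r2`, `n_obs` and the fitted `nlme::lme`
#'   model in `fit`.
#' @export
fit_zone_mixed_model <- function(monthly_means, plots, segment,
                                 variable = c("nh4", "po4"),
                                 years = NULL, alpha = 0.05) {
  variable <- match.arg(variable)
  stopifnot(is.data.frame(monthly_means), is.data.frame(plots))
  d <- dplyr::inner_join(monthly_means,
                         plots[, c("plot_id", "segment", "zone")],
                         by = "plot_id")
  d <- d[d$segment == segment, ]
  if (nrow(d) == 0) stop("no data for segment '", segment, "'")
  if (is.null(years)) years <- range(d$year)
  if (length(years) != 2) stop("exactly two years must be compared")
  d <- d[d$year %in% years & !is.na(d[[variable]]), ]
  if (!all(years %in% d$year)) {
    stop("both years (", paste(years, collapse = ", "),
         ") must be present in the data")
  }
  zones <- intersect(c("high", "mid", "low"), unique(d$zone))
  if (length(zones) < 2) {
    stop("segment '", segment, "' has a single zone; the zone model needs >= 2")
  }
  bad <- d[[variable]] <= 0
  if (any(bad)) {
    keys <- sprintf("%s %d-%02d", d$plot_id[bad], d$year[bad], d$month[bad])
    stop("non-positive ", variable, " concentration(s); cannot log-transform: ",
         paste(keys, collapse = "; "))
  }
  d$log_conc <- log(d[[variable]])
  d$zone <- factor(d$zone, levels = zones)
  d$yearf <- factor(d$year)
  d$year_month <- factor(paste(d$year, d$month, sep = "-"))
  fit <- nlme::lme(log_conc ~ zone * yearf, random = ~ 1 | year_month,
                   data = d, method = "REML")
  an <- stats::anova(fit)
  an <- an[rownames(an) != "(Intercept)", ]
  anova_tbl <- tibble::tibble(
    term = sub("yearf", "year", rownames(an), fixed = TRUE),
    num_df = as.integer(an$numDF),
    den_df = as.integer(an$denDF),
    f_value = an$`F-value`,
    p_value = an$`p-value`
  )
  vc <- suppressWarnings(as.numeric(nlme::VarCorr(fit)[, "Variance"]))
  vc <- vc[is.finite(vc)]  # order: month %in% year intercept, residual
  var_fixed <- var(predict(fit, level = 0))
  comps <- c(fixed = var_fixed, month_in_year = vc[1], residual = vc[2])
  r2 <- nakagawa_r2(var_fixed, vc[1], vc[2])
  structure(
    list(segment = segment, variable = variable, years = years,
         anova = anova_tbl, variance_components = comps,
         marginal_r2 = r2$marginal, conditional_r2 = r2$conditional,
         n_obs = nrow(d), alpha = alpha, fit = fit),
    class = "zone_model"
  )
}

#' @export
print.zone_model <- function(x, ...) {
  cat(sprintf("Zone x year mixed model: %s, segment %s (years %s; n = %d)\n",
              toupper(x$variable), x$segment,
              paste(x$years, collapse = " vs "), x$n_obs))
  print(as.data.frame(x$anova), row.names = FALSE, digits = 4)
  cat(sprintf("marginal R2 = %.4f, conditional R2 = %.4f\n",
              x$marginal_r2, x$conditional_r2))
  invisible(x)
}

#' Flatten zone-model results to a tidy table
#'
#' One row per fixed-effect term, mirroring the usual mixed-model ANOVA
#' report layout (response, segment, factor, DFs, F, p, marginal and
#' conditional R2).
#'
#' @param models A list of `zone_model` objects.
#' @return A tibble.
#' @export
zone_model_table <- function(models) {
  if (inherits(models, "zone_model")) models <- list(models)
  dplyr::bind_rows(lapply(models, function(m) {
    tibble::tibble(response = m$variable, segment = m$segment,
                   term = m$anova$term, num_df = m$anova$num_df,
                   den_df = m$anova$den_df, f_value = m$anova$f_value,
                   p_value = m$anova$p_value,
                   marginal_r2 = m$marginal_r2,
                   conditional_r2 = m$conditional_r2)
  }))
}
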