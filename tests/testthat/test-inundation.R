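test_that("constant series give the exact dry and wet extremes", {
  dry <- annual_inundation(full_year_series(2015, -1), 0, min_coverage_warn = 0)
  expect_identical(dry$hours_inundated, 0)
  expect_identical(dry$n_events, 0L)
  expect_identical(dry$percent_of_year, 0)
  expect_identical(dry$coverage, 1)

  wet <- annual_inundation(full_year_series(2015, 1), 0, min_coverage_warn = 0)
  expect_identical(wet$hours_inundated, 8760)
  expect_identical(wet$n_events, 1L)
  expect_identical(wet$percent_of_year, 100)
  expect_true(is.na(dry$mean_event_duration))
  expect_identical(wet$mean_event_duration, 8760)

  # leap year denominator
  wet16 <- annual_inundation(full_year_series(2016, 1), 0, min_coverage_warn = 0)
  expect_identical(wet16$hours_inundated, 8784)
  expect_identical(wet16$percent_of_year, 100)
})

test_that("a zero-mean sinusoid floods a plot at datum half the year", {
  wl <- full_year_series(2015, function(i) sin(2 * pi * (i / 10) / 12.42))
  s <- annual_inundation(wl, 0, min_coverage_warn = 0)
  # exact agreement with a direct count of strictly positive samples
  expect_identical(s$hours_inundated, sum(wl$levels > 0) * 0.1)
  expect_equal(s$percent_of_year, 50, tolerance = 0.2)
})

test_that("ties count dry under strict exceedance", {
  wl <- water_level_series(c(0, 0, 1, 0, 1, 1), "2015-06-01 00:00")
  s <- annual_inundation(wl, 0, min_coverage_warn = 0)
  expect_identical(s$hours_inundated, 0.3)
  expect_identical(s$n_events, 2L)
})

test_that("missing samples break events, count dry, and reduce coverage", {
  lev <- c(1, 1, NA, 1, 1, 0, 1)
  wl <- water_level_series(lev, "2015-06-01 00:00")
  s <- annual_inundation(wl, 0, min_coverage_warn = 0)
  expect_identical(s$hours_inundated, 0.5)
  expect_identical(s$n_events, 3L)
  expect_identical(s$coverage, 6 / (8760 * 10))

  # year with no usable data: coverage 0, metrics missing
  wl2 <- water_level_series(rep(NA_real_, 5), "2015-06-01 00:00")
  s2 <- annual_inundation(wl2, 0, min_coverage_warn = 0)
  expect_identical(s2$coverage, 0)
  expect_true(is.na(s2$hours_inundated) && is.na(s2$n_events))
})

test_that("low data coverage raises a warning", {
  wl <- water_level_series(rep(1, 1000), "2015-06-01 00:00")
  expect_warning(annual_inundation(wl, 0), "coverage below 95%")
})

test_that("datum mismatch refuses to compute", {
  wl <- water_level_series(rep(1, 10), "2015-06-01 00:00", datum = "MSL")
  expect_error(annual_inundation(wl, 0), "datum mismatch")
  expect_no_error(annual_inundation(wl, 0, elevation_datum = "MSL",
                                    min_coverage_warn = 0))
})

test_that("summaries match the brute-force counter on random series", {
  withr::local_seed(101)
  for (k in 1:12) {
    wl <- random_series(n = sample(100:5000, 1))
    elev <- stats::quantile(wl$levels, runif(1), na.rm = TRUE)
    got <- annual_inundation(wl, elev, min_coverage_warn = 0)
    want <- brute_force_inundation(wl, elev)
    expect_equal(as.data.frame(got), want, tolerance = 0)
  }
})

test_that("summaries are invariant to a common vertical shift", {
  withr::local_seed(7)
  wl <- random_series(n = 2000)
  elev <- 0.2
  a <- annual_inundation(wl, elev, min_coverage_warn = 0)
  wl2 <- wl
  wl2$levels <- wl$levels + 1.234
  b <- annual_inundation(wl2, elev + 1.234, min_coverage_warn = 0)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("event accounting identity holds across random series", {
  withr::local_seed(55)
  for (k in 1:5) {
    wl <- random_series(n = 3000)
    s <- annual_inundation(wl, 0, min_coverage_warn = 0)
    ok <- !is.na(s$n_events) & s$n_events > 0
    expect_equal(s$n_events[ok] * s$mean_event_duration[ok],
                 s$hours_inundated[ok], tolerance = 1e-12)
    expect_true(all(s$coverage >= 0 & s$coverage <= 1))
    expect_true(all(s$percent_of_year[!is.na(s$percent_of_year)] <= 100))
  }
})

test_that("inundation_table covers every plot-year and is elevation-monotone", {
  wl <- simulate_water_levels(tide_config(end = "2011-01-01 00:00", seed = 2))
  plots <- simulate_marsh(marsh_config())[c(1, 9, 20, 30, 51), ]
  tab <- inundation_table(wl, plots)
  expect_identical(nrow(tab), nrow(plots) * 2L)
  merged <- merge(tab, plots[, c("plot_id", "elevation")], by = "plot_id")
  for (y in unique(merged$year)) {
    d <- merged[merged$year == y, ]
    d <- d[order(d$elevation), ]
    expect_true(all(diff(d$hours_inundated) <= 0))
  }
  # a plot below the series minimum is wet whenever data are present
  bottom <- min(wl$levels, na.rm = TRUE) - 1
  s <- annual_inundation(wl, bottom, min_coverage_warn = 0)
  expect_equal(s$hours_inundated, s$coverage * 8760, tolerance = 1e-12)
})

test_that("MHHW reduces to level for constants and amplitude for sinusoids", {
  wl <- water_level_series(rep(0.42, 10000), "2015-01-01 00:00")
  expect_identical(compute_mhhw(wl), 0.42)

  wl2 <- full_year_series(2015, function(i) 0.8 * sin(2 * pi * (i / 10) / 12.42))
  expect_equal(compute_mhhw(wl2), 0.8, tolerance = 1e-3)

  expect_error(compute_mhhw(wl, epoch_start = "2020-01-01", epoch_end = "2020-02-01"),
               "empty epoch")
  wl3 <- water_level_series(c(rep(NA_real_, 9000), rep(1, 1000)), "2015-01-01 00:00")
  expect_error(compute_mhhw(wl3), "insufficient coverage")
})

test_that("monthly mean sea level handles gaps and preserves constants", {
  wl <- simulate_water_levels(tide_config(mean_level = 0.2, constituents = list(),
                                          slr_trend = 0, seasonal_amplitude = 0,
                                          noise_sd = 0, end = "2009-07-01 00:00"))
  m <- monthly_mean_sea_level(wl)
  expect_identical(nrow(m), 6L)
  expect_true(all(m$msl == 0.2))

  # knock out all of March
  mar <- format(wl_timestamps(wl), "%m") == "03"
  wl$levels[mar] <- NA
  m2 <- monthly_mean_sea_level(wl)
  expect_true(is.na(m2$msl[m2$month == 3]))
  expect_identical(nrow(m2), 6L)
})

test_that("seasonal adjustment removes a repeating annual cycle exactly", {
  months <- expand.grid(month = 1:12, year = 2009:2012)
  cyc <- tibble::tibble(year = months$year, month = months$month,
                        msl = 0.3 + 0.1 * sin(2 * pi * months$month / 12))
  adj <- seasonally_adjust(cyc)
  expect_equal(adj$msl_adj, rep(0.3, 48), tolerance = 1e-12)
  tr <- fit_linear_trend(adj$year, adj$msl_adj)
  expect_equal(tr$slope, 0, tolerance = 1e-12)

  expect_error(seasonally_adjust(cyc[1:20, ]), "24 non-missing months")
})
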