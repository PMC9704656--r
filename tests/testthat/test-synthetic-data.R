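test_that("water-level generator reduces to its deterministic parts", {
  # degenerate config: no forcing at all -> identically zero
  cfg0 <- tide_config(mean_level = 0, constituents = list(), slr_trend = 0,
                      seasonal_amplitude = 0, noise_sd = 0,
                      start = "2009-01-01 00:00", end = "2009-02-01 00:00")
  expect_true(all(simulate_water_levels(cfg0)$levels == 0))

  # pure linear forcing: 13.2 mm/yr gives exactly 0.0132 m one Julian year in
  cfg1 <- tide_config(mean_level = 0, constituents = list(), slr_trend = 13.2,
                      seasonal_amplitude = 0, noise_sd = 0)
  wl <- simulate_water_levels(cfg1)
  i_year <- 365.25 * 24 * 10 + 1  # 6-min samples to t = 365.25 d, 1-based
  expect_identical(i_year, round(i_year))
  expect_equal(wl$levels[i_year], 0.0132, tolerance = 1e-12)

  # single sinusoidal constituent sampled over whole periods: variance ~ 1/2
  cfg2 <- tide_config(mean_level = 0, slr_trend = 0, seasonal_amplitude = 0,
                      noise_sd = 0,
                      constituents = list(c(amplitude = 1, period = 12, phase = 0)),
                      start = "2009-01-01 00:00", end = "2009-01-06 00:00")
  v <- var(simulate_water_levels(cfg2)$levels)
  n <- 5 * 240
  expect_equal(v, 0.5 * n / (n - 1), tolerance = 1e-10)
})

test_that("water-level generator is seed-deterministic and level-linear", {
  a <- simulate_water_levels(tide_config(seed = 11, end = "2009-03-01 00:00"))
  b <- simulate_water_levels(tide_config(seed = 11, end = "2009-03-01 00:00"))
  c <- simulate_water_levels(tide_config(seed = 12, end = "2009-03-01 00:00"))
  expect_identical(a$levels, b$levels)
  expect_false(identical(a$levels, c$levels))

  shifted <- simulate_water_levels(tide_config(mean_level = 0.37, seed = 11,
                                               end = "2009-03-01 00:00"))
  expect_equal(shifted$levels, a$levels + 0.37, tolerance = 1e-12)
})

test_that("tide_config rejects invalid windows, intervals and noise", {
  expect_error(tide_config(start = "2010-01-01", end = "2009-01-01"), "after start")
  expect_error(tide_config(interval = 7), "divide 60")
  expect_error(tide_config(noise_sd = -1), "noise_sd")
  expect_error(tide_config(constituents = list(c(amplitude = -1, period = 12, phase = 0))),
               "amplitude")
})

test_that("default marsh layout reproduces the monitoring design", {
  plots <- simulate_marsh(marsh_config())
  expect_identical(nrow(plots), 51L)
  expect_identical(nrow(unique(plots[, c("segment", "transect")])), 6L)
  counts <- table(plots$segment[!duplicated(paste(plots$segment, plots$transect))])
  expect_true(all(table(plots$segment, plots$transect) %in% c(0, 8, 9)))

  a <- plots[plots$segment == "A", ]
  expect_equal(min(a$elevation), -0.467, tolerance = 0.05)
  expect_equal(max(a$elevation), 1.09, tolerance = 0.05)

  # Segment B has no mid-marsh zone
  expect_identical(sum(plots$zone == "mid" & plots$segment == "B"), 0L)
  expect_setequal(unique(plots$zone[plots$segment == "B"]), c("high", "low"))

  # base profile descends from forest edge to creek; jitter is small
  for (tr in 1:3) {
    e <- a$elevation[a$transect == tr]
    expect_true(all(diff(e) < 0.05))
  }
})

test_that("marsh generator validates zone boundaries and plot counts", {
  expect_error(marsh_segment(zone_breaks = c(0.45, 2)), "outside")
  expect_error(marsh_segment(plots_per_transect = 5), "8 or 9")
  expect_error(marsh_segment(zone_breaks = 0.5, zone_labels = c("low", "mid", "high")),
               "one more zone label")
})

test_that("porewater generator honours its degenerate and exact cases", {
  plots <- simulate_marsh(marsh_config(elev_jitter_sd = 0))
  rates <- default_inundation_rates(plots)
  base <- porewater_config(
    coupling_nh4 = 0, coupling_po4 = 0,
    month_effects = list(nh4 = rep(0, 4), po4 = rep(0, 4), salinity = rep(0, 4)),
    noise_sd = list(nh4 = c(high = 0, mid = 0, low = 0),
                    po4 = c(high = 0, mid = 0, low = 0),
                    salinity = c(high = 0, mid = 0, low = 0)),
    salinity_trend = 0
  )
  pw <- simulate_porewater(plots, rates, base)
  zone <- plots$zone[match(pw$plot_id, plots$plot_id)]
  expect_identical(pw$nh4, unname(base$baseline$nh4[zone]))
  expect_identical(pw$po4, unname(base$baseline$po4[zone]))

  # replicate and month structure
  expect_identical(nrow(pw), 51L * 11L * 4L * 3L)
  expect_true(all(pw$month %in% 5:8))
  per_pm <- table(paste(pw$plot_id, pw$year, pw$month))
  expect_true(all(per_pm == 3))

  # noiseless coupling gamma and plot rate r: slope of yearly means is gamma*r
  g <- 0.05
  cfg <- porewater_config(coupling_nh4 = g, coupling_po4 = 0,
                          month_effects = base$month_effects,
                          noise_sd = base$noise_sd, salinity_trend = 0)
  pw2 <- simulate_porewater(plots, rates, cfg)
  p1 <- plots$plot_id[plots$zone == "low"][1]
  ym <- aggregate(nh4 ~ year, data = pw2[pw2$plot_id == p1, ], FUN = mean)
  tr <- fit_linear_trend(ym$year, ym$nh4)
  expect_equal(tr$slope, g * unname(rates[p1]), tolerance = 1e-9)
})

test_that("porewater concentrations never fall below the detection floor", {
  plots <- simulate_marsh(marsh_config())
  rates <- default_inundation_rates(plots)
  cfg <- porewater_config(detection_floor = 5,
                          noise_sd = list(nh4 = c(high = 80, mid = 80, low = 80),
                                          po4 = c(high = 20, mid = 20, low = 20),
                                          salinity = c(high = 3, mid = 3, low = 3)),
                          seed = 9)
  pw <- simulate_porewater(plots, rates, cfg)
  expect_gte(min(pw$nh4), 5)
  expect_gte(min(pw$po4), 5)
  expect_gte(min(pw$salinity), 0)
})

test_that("porewater generator requires a rate for every plot", {
  plots <- simulate_marsh(marsh_config())
  rates <- default_inundation_rates(plots)
  expect_error(simulate_porewater(plots, rates[-1]), "missing inundation rate")
})

test_that("default couplings are calibrated to the target low-marsh rates", {
  cfg <- porewater_config()
  r_low <- nominal_low_marsh_rate()
  expect_equal(cfg$coupling_nh4 * r_low, 8.96, tolerance = 1e-12)
  expect_equal(cfg$coupling_po4 * r_low, 0.86, tolerance = 1e-12)
})

test_that("mean plot-level slope recovers the configured coupling", {
  # stochastic parameter-recovery at small scale: mean over replicate
  # datasets of the OLS slope at one plot approaches gamma * r
  plots <- simulate_marsh(marsh_config(elev_jitter_sd = 0))
  rates <- default_inundation_rates(plots)
  p1 <- plots$plot_id[plots$zone == "low"][4]
  cfg0 <- porewater_config()
  slopes <- vapply(1:25, function(s) {
    cfg <- porewater_config(seed = 100 + s)
    pw <- simulate_porewater(plots[plots$plot_id == p1, ], rates, cfg)
    mm <- monthly_plot_means(pw)
    fit_linear_trend(mm$year, mm$nh4)$slope
  }, numeric(1))
  truth <- cfg0$coupling_nh4 * unname(rates[p1])
  expect_lt(abs(mean(slopes) - truth), 3 * sd(slopes) / sqrt(length(slopes)))
})
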