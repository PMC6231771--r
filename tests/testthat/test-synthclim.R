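test_that("noise-free generator reproduces the deterministic seasonal curve", {
  cp <- climate_params(noise_sd = 0, year_offsets_sd = 0, warming_trend = 0,
                       n_years = 3, seed = 5)
  clim <- generate_temperature_series(cp)
  expect_equal(nrow(clim), 3 * 365)
  y1 <- clim$temp[clim$year == 2001]
  expect_equal(clim$temp[clim$year == 2002], y1)
  expect_equal(clim$temp[clim$year == 2003], y1)
  expect_equal(y1, 9 + 9.5 * cos(2 * pi * ((1:365) - 200) / 365))
  expect_equal(which.max(y1), 200)   # mid-summer warmest
})

test_that("year offsets shift a year's temperatures additively", {
  base <- generate_temperature_series(
    climate_params(n_years = 2, seed = 9, year_offsets = c(0, 0)))
  lifted <- generate_temperature_series(
    climate_params(n_years = 2, seed = 9, year_offsets = c(0, 1)))
  expect_equal(lifted$temp[lifted$year == 2002],
               base$temp[base$year == 2002] + 1)
  expect_equal(lifted$temp[lifted$year == 2001],
               base$temp[base$year == 2001])
})

test_that("identical parameters and seed give bit-identical series", {
  cp <- climate_params(n_years = 2, seed = 123, resolution = "6-hourly")
  expect_identical(generate_temperature_series(cp),
                   generate_temperature_series(cp))
})

test_that("sub-daily resolutions preserve the daily mean exactly", {
  for (res in c("hourly", "6-hourly")) {
    cp <- climate_params(n_years = 1, seed = 4, resolution = res)
    clim <- generate_temperature_series(cp)
    cp_daily <- climate_params(n_years = 1, seed = 4)
    daily <- generate_temperature_series(cp_daily)
    expect_equal(.subset2(phenosync:::.as_daily(clim), "temp"), daily$temp)
  }
})

test_that("generator rejects invalid parameters", {
  expect_error(climate_params(n_years = 0),
               class = "phenosync_invalid_parameter")
  expect_error(climate_params(noise_autocorr = 1),
               class = "phenosync_invalid_parameter")
})

test_that("pure degree-day individuals leaf out at ceil(F/(T-5))", {
  pop <- population_spec(n_individuals = 6, daylength_sens_mean = 0,
                         daylength_sens_sd = 0, chilling_sens_mean = 0,
                         chilling_sens_sd = 0, seed = 2)
  clim <- make_climate(12)   # 7 DD per day
  ev <- simulate_events(pop, clim)
  traits <- draw_individual_traits(pop)
  expect_equal(ev$doy, as.integer(ceiling(traits$forcing_req / 7)))
})

test_that("short-day sensitivity delays the event relative to an insensitive twin", {
  clim <- make_climate(12)
  base <- population_spec(n_individuals = 1, forcing_req_sd = 0,
                          daylength_sens_mean = 0, daylength_sens_sd = 0,
                          chilling_sens_mean = 0, chilling_sens_sd = 0, seed = 1)
  sens <- population_spec(n_individuals = 1, forcing_req_sd = 0,
                          daylength_sens_mean = -20, daylength_sens_sd = 0,
                          chilling_sens_mean = 0, chilling_sens_sd = 0, seed = 1)
  d0 <- simulate_events(base, clim)$doy
  d1 <- simulate_events(sens, clim)$doy
  expect_lt(day_length(48.5, d1), 16)   # crossing happens under short days
  expect_gt(d1, d0)
})

test_that("zero trait heterogeneity gives zero within-year spread", {
  pop <- population_spec(n_individuals = 8, forcing_req_sd = 0,
                         daylength_sens_sd = 0, chilling_sens_sd = 0, seed = 3)
  clim <- generate_temperature_series(climate_params(n_years = 3, seed = 8))
  ev <- simulate_events(pop, clim)
  spread <- tapply(ev$doy, ev$year, function(x) sd(x[!is.na(x)]))
  expect_true(all(spread == 0, na.rm = TRUE))
})

test_that("warming increases the spread of dates in day-length-diverse populations", {
  # direct-simulation oracle, majority sign over seeds
  wins <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    pop <- population_spec(n_individuals = 15, forcing_req_sd = 0,
                           chilling_sens_mean = 0, chilling_sens_sd = 0,
                           seed = 400 + s)
    cold <- generate_temperature_series(
      climate_params(n_years = 1, seed = 600 + s, year_offsets = 0))
    warm <- cold; warm$temp <- warm$temp + 3
    sd_cold <- sd(simulate_events(pop, cold)$doy, na.rm = TRUE)
    sd_warm <- sd(simulate_events(pop, warm)$doy, na.rm = TRUE)
    if (isTRUE(sd_warm > sd_cold)) wins <- wins + 1L
  }
  expect_gt(wins, n_seeds / 2)
})

test_that("records round-trip through the CSV dialect", {
  pop <- population_spec(n_individuals = 3, seed = 6)
  clim <- generate_temperature_series(climate_params(n_years = 3, seed = 12))
  ev <- simulate_events(pop, clim)   # first year skipped (no preceding autumn)
  expect_setequal(unique(ev$year), c(2002, 2003))
  path <- withr::local_tempfile(fileext = ".csv")
  emit_records(ev, path)
  back <- read_pheno_csv(path)
  expect_equal(nrow(back), sum(!is.na(ev$doy)))
  expect_equal(back$doy, ev$doy[!is.na(ev$doy)])
  expect_equal(back$lat, ev$lat[!is.na(ev$doy)], tolerance = 1e-12)
})

test_that("unreached requirements are flagged missing, not dropped", {
  pop <- population_spec(n_individuals = 4, forcing_req_mean = 5000,
                         forcing_req_sd = 0, daylength_sens_sd = 0,
                         chilling_sens_mean = 0, chilling_sens_sd = 0, seed = 2)
  ev <- simulate_events(pop, make_climate(12))
  expect_equal(nrow(ev), 4)
  expect_true(all(is.na(ev$doy)))
  path <- withr::local_tempfile(fileext = ".csv")
  emit_records(ev, path)
  expect_equal(nrow(read.csv(path)), 0)
})

test_that("climate CSV round-trips through ISO timestamps", {
  clim <- generate_temperature_series(
    climate_params(n_years = 1, seed = 3, resolution = "6-hourly"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_climate_csv(clim, path)
  back <- read_climate_csv(path)
  expect_equal(back$temp, clim$temp)
  expect_equal(back$doy, clim$doy)
  expect_equal(attr(back, "step_hours"), 6)
})
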