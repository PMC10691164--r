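test_that("buffer min/median match an exhaustive brute-force enumeration", {
  for (s in 1:3) {
    land <- simulate_landscape(landscape_config(grid_shape = c(40, 40),
                                                n_refugia_patches = 4,
                                                seed = 100 + s))
    set.seed(s)
    n <- 15
    lon <- runif(n, min(land$cell_lon), max(land$cell_lon))
    lat <- runif(n, min(land$cell_lat), max(land$cell_lat))
    ts <- as.POSIXct("2015-06-01 00:00", tz = "UTC") +
      round(runif(n, 0, 90 * 86400))
    fx <- tibble::tibble(bird_id = "x", timestamp = ts, lon = lon, lat = lat)
    env <- sample_environment(fx, land)
    for (i in seq_len(n)) {
      hr <- migcues:::nearest_hour(ts[i])
      oracle <- brute_force_buffer(land, lon[i], lat[i], hr$date, hr$hour)
      expect_identical(env$buffer_min_C[i], oracle$min)
      expect_equal(env$buffer_median_C[i], oracle$median, tolerance = 1e-12)
      expect_identical(env$refugia_flag[i],
                       (oracle$median - oracle$min) >= 0.5)
    }
  }
})

test_that("the refugium threshold is inclusive at exactly 0.5 degrees", {
  expect_true(refugia_indicator(29.4, 30.0))   # gap 0.6
  expect_true(refugia_indicator(29.5, 30.0))   # gap exactly 0.5
  expect_false(refugia_indicator(29.6, 30.0))  # gap 0.4
  expect_false(refugia_indicator(25.0, 25.0))  # no gap
  expect_error(refugia_indicator(30.5, 30.0), "upstream")
})

test_that("NDVI follows the reflectance formula", {
  expect_equal(ndvi_from_reflectance(0.4, 0.1), 0.6)
  expect_equal(ndvi_from_reflectance(0.3, 0.3), 0)
  expect_equal(ndvi_from_reflectance(0.5, 0), 1)
  expect_warning(out <- ndvi_from_reflectance(0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("fixes match the nearest composite, earlier on ties", {
  land <- test_landscape(seed = 51)
  # composites every 8 days from 1 April: 2015-04-01, 2015-04-09, ...
  expect_identical(
    migcues:::nearest_composite(land$composite_dates, as.Date("2015-04-08")),
    as.Date("2015-04-09"))
  expect_identical(
    migcues:::nearest_composite(land$composite_dates, as.Date("2015-04-05")),
    as.Date("2015-04-01"))
  # constant-NDVI landscape: every fix gets the cell constant
  flat <- simulate_landscape(landscape_config(grid_shape = c(40, 40),
                                              ndvi_senescence_rate = 0,
                                              seed = 52))
  lon <- flat$cell_lon[20]; lat <- flat$cell_lat[20]
  fx <- tibble::tibble(
    bird_id = "x",
    timestamp = as.POSIXct("2015-05-01 12:00", tz = "UTC") +
      (0:9) * 10 * 86400,
    lon = lon, lat = lat)
  env <- sample_environment(fx, flat)
  expect_true(all(env$ndvi == env$ndvi[1]))
  expect_equal(env$ndvi[1], flat$greenness[20, 20])
})

test_that("on a uniform grid point, min and median coincide and nothing is a refugium", {
  land <- simulate_landscape(landscape_config(grid_shape = c(40, 40),
                                              noise_sd_C = 0,
                                              n_refugia_patches = 1,
                                              seed = 53))
  land$anomaly[] <- 0  # remove the single mandatory patch for a uniform field
  fx <- tibble::tibble(bird_id = "x",
                       timestamp = as.POSIXct("2015-06-15 10:00", tz = "UTC"),
                       lon = land$cell_lon[20], lat = land$cell_lat[20])
  env <- sample_environment(fx, land)
  expect_equal(env$point_temp_C, env$buffer_min_C)
  expect_equal(env$buffer_min_C, env$buffer_median_C)
  expect_false(env$refugia_flag)
})

test_that("seasonal refugia percentages count fixes, not days", {
  land <- test_landscape(seed = 54)
  base <- tibble::tibble(
    bird_id = "x",
    timestamp = as.POSIXct("2015-05-02 06:00", tz = "UTC") + (0:9) * 3600,
    lon = land$cell_lon[50], lat = land$cell_lat[50])
  env <- sample_environment(base, land)
  env$refugia_flag <- rep(c(TRUE, FALSE), c(4, 6))
  s <- summarize_season(env, c(as.Date("2015-05-01"), as.Date("2015-05-31")))
  expect_equal(s$refugia_pct, 40)
  env$refugia_flag <- TRUE
  expect_equal(summarize_season(env, c(as.Date("2015-05-01"),
                                       as.Date("2015-05-31")))$refugia_pct, 100)
  expect_error(summarize_season(env, c(as.Date("2015-07-01"),
                                       as.Date("2015-07-31"))),
               "empty_window")
})

test_that("refugia percentage is invariant to uniform grid warming", {
  land <- simulate_landscape(landscape_config(grid_shape = c(40, 40),
                                              n_refugia_patches = 3,
                                              seed = 55))
  warm <- simulate_landscape(landscape_config(grid_shape = c(40, 40),
                                              n_refugia_patches = 3,
                                              base_diel_cycle = c(23, 41),
                                              seed = 55))
  set.seed(55)
  n <- 30
  fx <- tibble::tibble(
    bird_id = "x",
    timestamp = as.POSIXct("2015-06-01 00:00", tz = "UTC") +
      round(runif(n, 0, 60 * 86400)),
    lon = runif(n, min(land$cell_lon), max(land$cell_lon)),
    lat = runif(n, min(land$cell_lat), max(land$cell_lat)))
  a <- sample_environment(fx, land)
  b <- sample_environment(fx, warm)
  expect_identical(a$refugia_flag, b$refugia_flag)
  expect_equal(b$point_temp_C - a$point_temp_C, rep(5, n))
})

test_that("day averages are invariant to fix order within a day", {
  land <- test_landscape(seed = 56)
  fx <- tibble::tibble(
    bird_id = "x",
    timestamp = as.POSIXct("2015-05-10 00:00", tz = "UTC") +
      c(2, 8, 14, 20) * 3600,
    lon = land$cell_lon[45] + c(0, 1e-4, -1e-4, 0),
    lat = land$cell_lat[45] + c(1e-4, 0, 0, -1e-4))
  env <- sample_environment(fx, land)
  shuffled <- env[c(3, 1, 4, 2), ]
  expect_equal(daily_env(env), daily_env(shuffled))
})

test_that("a bird parked on a cooled patch has 100% refugia availability", {
  land <- simulate_landscape(landscape_config(grid_shape = c(60, 60),
                                              noise_sd_C = 0,
                                              refugia_cooling_C = 1.0,
                                              n_refugia_patches = 1,
                                              seed = 57))
  # place the cooled patch at the grid centre so every buffer is complete
  land$refugia_mask[] <- FALSE
  land$refugia_mask[29:31, 29:31] <- TRUE
  land$anomaly <- -1.0 * land$refugia_mask
  r <- c(30, 30)
  fx <- tibble::tibble(
    bird_id = "x",
    timestamp = as.POSIXct("2015-05-02 00:00", tz = "UTC") + (0:47) * 7200,
    lon = land$cell_lon[r[2]], lat = land$cell_lat[r[1]])
  env <- sample_environment(fx, land)
  s <- summarize_season(env, c(as.Date("2015-05-01"), as.Date("2015-05-31")))
  expect_equal(s$refugia_pct, 100)
})
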