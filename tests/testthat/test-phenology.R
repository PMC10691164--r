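test_that("daily centroids are per-day arithmetic means", {
  t0 <- as.POSIXct("2015-05-01 00:00", tz = "UTC")
  fx <- tibble::tibble(bird_id = "a",
                       timestamp = t0 + c(0, 6, 12, 18) * 3600,
                       lon = 0.5, lat = 38.0)
  cc <- daily_centroids(fx)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$lon, 0.5); expect_equal(cc$lat, 38.0)
  expect_equal(cc$n_fixes, 4L)

  fx2 <- tibble::tibble(bird_id = "a", timestamp = t0 + c(0, 3600),
                        lon = c(0.00, 0.02), lat = 38.0)
  expect_equal(daily_centroids(fx2)$lon, 0.01)
})

test_that("duplicate fixes are dropped with a warning; bad timestamps error", {
  t0 <- as.POSIXct("2015-05-01 00:00", tz = "UTC")
  fx <- tibble::tibble(bird_id = "a", timestamp = t0 + c(0, 0, 3600),
                       lon = c(0, 0, 1), lat = 38)
  expect_warning(cc <- daily_centroids(fx), "duplicate")
  expect_equal(cc$n_fixes, 2L)
  bad <- tibble::tibble(bird_id = "a", timestamp = c("2015-05-01 08:00:00",
                                                     "not a time"),
                        lon = 0, lat = 38)
  expect_error(daily_centroids(bad), "row 2")
})

test_that("the breeding reference requires 7 window days and averages centroids", {
  days <- seq(as.Date("2015-04-01"), by = 1, length.out = 10)
  cc <- tibble::tibble(bird_id = "a", date = days, lon = 0.5, lat = 38,
                       n_fixes = 2L)
  ref <- breeding_reference(cc, c(days[1], days[10]))
  expect_equal(c(ref$lon, ref$lat), c(0.5, 38))
  expect_equal(ref$n_days, 10)
  expect_error(breeding_reference(cc, c(days[1], days[6])),
               "insufficient_predeparture_days")
})

test_that("departure follows the sustained one-month rule", {
  site <- c(-7.0, 38.5); away <- c(-6.5, 38.9)  # ~ 62 km
  ref <- list(lon = site[1], lat = site[2])
  # away for 60 days from 20 June -> departure 20 June
  fx <- manual_fixes(site = site, from = "2015-04-10", to = "2015-09-15",
                     departure = "2015-06-20", away_site = away)
  cc <- daily_centroids(fx)
  d <- detect_departure(cc, ref)
  expect_equal(d$status, "migrant")
  expect_equal(d$departure_date, as.Date("2015-06-20"))

  # a 20-day excursion does not qualify: resident
  fx2 <- manual_fixes(site = site, from = "2015-04-10", to = "2015-09-15",
                      departure = "2015-06-20", back = "2015-07-10",
                      away_site = away)
  d2 <- detect_departure(daily_centroids(fx2), ref)
  expect_equal(d2$status, "resident")

  # track ends 10 days into the away run: censored, no date emitted
  fx3 <- manual_fixes(site = site, from = "2015-04-10", to = "2015-06-29",
                      departure = "2015-06-20", away_site = away)
  d3 <- detect_departure(daily_centroids(fx3), ref)
  expect_equal(d3$status, "censored")
  expect_true(is.na(d3$departure_date))
})

test_that("observation gaps up to 3 days bridge an away run, longer ones break it", {
  site <- c(-7.0, 38.5); away <- c(-6.5, 38.9)
  ref <- list(lon = site[1], lat = site[2])
  fx <- manual_fixes(site = site, from = "2015-04-10", to = "2015-09-15",
                     departure = "2015-06-20", away_site = away)
  # remove 3 observed days inside the away run: still one run
  drop3 <- as.Date(c("2015-07-01", "2015-07-02", "2015-07-03"))
  cc <- daily_centroids(fx[!as.Date(fx$timestamp) %in% drop3, ])
  expect_equal(detect_departure(cc, ref)$departure_date,
               as.Date("2015-06-20"))
  # a 25-day hole straight after a 9-day away stretch breaks the run; the
  # departure resolves at the resumed away stretch
  hole <- seq(as.Date("2015-06-29"), as.Date("2015-07-23"), by = 1)
  cc2 <- daily_centroids(fx[!as.Date(fx$timestamp) %in% hole, ])
  expect_equal(detect_departure(cc2, ref)$departure_date,
               as.Date("2015-07-24"))
})

test_that("return detection finds the sustained home run or censors", {
  site <- c(-7.0, 38.5); away <- c(-6.5, 38.9)
  ref <- list(lon = site[1], lat = site[2])
  fx <- manual_fixes(site = site, from = "2015-04-10", to = "2016-01-31",
                     departure = "2015-06-20", back = "2015-11-29",
                     away_site = away)
  cc <- daily_centroids(fx)
  r <- detect_return(cc, ref, as.Date("2015-06-20"))
  expect_equal(r$return_date, as.Date("2015-11-29"))
  expect_equal(r$censoring_reason, "none")

  # track ends in October while away: censored
  fx2 <- manual_fixes(site = site, from = "2015-04-10", to = "2015-10-15",
                      departure = "2015-06-20", away_site = away)
  r2 <- detect_return(daily_centroids(fx2), ref, as.Date("2015-06-20"))
  expect_true(is.na(r2$return_date))
  expect_equal(r2$censoring_reason, "track_ended")
})

test_that("migration distance: parked 100 km away for 10 days", {
  ref <- list(lon = -7.0, lat = 38.5)
  p <- geosphere::destPoint(c(-7.0, 38.5), 45, 100000)
  days <- seq(as.Date("2015-07-01"), by = 1, length.out = 10)
  cc <- tibble::tibble(bird_id = "a", date = days,
                       lon = p[1], lat = p[2], n_fixes = 2L)
  md <- migration_distance(cc, ref, days[1], days[10])
  expect_equal(md$distance_cumulative_km, 1000, tolerance = 1e-9)
  expect_equal(md$distance_site_km, 100, tolerance = 1e-9)
  expect_error(migration_distance(cc, ref, as.Date(NA), days[10]),
               "departure")
})

test_that("noiseless synthetic cohorts are recovered exactly", {
  land <- test_landscape(seed = 41)
  sim <- simulate_tracks(land, n_birds = 12, n_residents = 2,
                         gps_noise_sd_m = 0, home_range_sd_m = 0, seed = 41)
  ev <- migration_events(sim$fixes)
  m <- dplyr::inner_join(ev, sim$truth, by = c("bird_id", "season_year"))
  expect_equal(nrow(m), 12)
  expect_identical(m$strategy.x, m$strategy.y)
  mig <- m[m$strategy.x == "migrant", ]
  expect_identical(mig$departure_date, mig$true_departure_date)
  expect_identical(mig$return_date, mig$true_return_date)
  expect_true(all(abs(mig$distance_site_km - mig$distance_km) /
                    mig$distance_km < 0.01))
  # residents emit no dates
  res <- m[m$strategy.x == "resident", ]
  expect_true(all(is.na(res$departure_date)) && all(is.na(res$return_date)))
})

test_that("departure detection is invariant to fix frequency on noiseless tracks", {
  land <- test_landscape(seed = 42)
  a <- simulate_tracks(land, n_birds = 4, n_residents = 0, gps_noise_sd_m = 0,
                       home_range_sd_m = 0, fix_interval_min = 120, seed = 42)
  b <- simulate_tracks(land, n_birds = 4, n_residents = 0, gps_noise_sd_m = 0,
                       home_range_sd_m = 0, fix_interval_min = 30, seed = 42)
  ea <- migration_events(a$fixes); eb <- migration_events(b$fixes)
  expect_identical(ea$departure_date, eb$departure_date)
})

test_that("late tracking starts and short pre-departure windows are excluded", {
  # capture after the 1 May deadline
  late <- manual_fixes(from = "2015-05-10", to = "2015-09-15")
  ev <- migration_events(late)
  expect_equal(nrow(ev), 0)
  expect_equal(phenology_exclusions(ev)$reason, "capture_after_season_start")
  # only 5 pre-departure days
  short <- manual_fixes(site = c(-7.0, 38.5), from = "2015-04-26",
                        to = "2015-09-15", departure = "2015-05-01",
                        away_site = c(-6.5, 38.9))
  ev2 <- migration_events(short)
  expect_equal(nrow(ev2), 0)
  expect_equal(phenology_exclusions(ev2)$reason,
               "insufficient_predeparture_days")
})

test_that("season years split at 1 April and returns attach to the breeding season", {
  expect_equal(migcues:::season_year_of(as.Date("2015-04-01")), 2015L)
  expect_equal(migcues:::season_year_of(as.Date("2016-01-15")), 2015L)
  expect_equal(migcues:::season_year_of(as.Date("2016-03-31")), 2015L)
  expect_equal(migcues:::season_year_of(as.Date("2016-04-01")), 2016L)
})
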