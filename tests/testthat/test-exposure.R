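daily_frame <- function(dates, values, bird = "a") {
  tibble::tibble(bird_id = bird, date = as.Date(dates, origin = "1970-01-01"),
                 point_temp_C = values, buffer_min_C = values - 1,
                 buffer_median_C = values, ndvi = 0.5, n_samples = 4L)
}

test_that("the population smooth reproduces linear and constant signals", {
  dates <- seq(as.Date("2015-05-01"), by = 1, length.out = 60)
  y <- 20 + 0.1 * seq_along(dates)
  sm <- fit_population_smooth(daily_frame(dates, y), "temperature")
  fitted <- predict(sm, doy(dates))
  expect_equal(fitted, y, tolerance = 1e-6)

  expect_warning(
    smc <- fit_population_smooth(daily_frame(dates, rep(25, 60)),
                                 "temperature"),
    "constant")
  expect_equal(predict(smc, doy(dates)), rep(25, 60), tolerance = 1e-8)
})

test_that("too few days or out-of-range prediction raise errors", {
  dates <- seq(as.Date("2015-05-01"), by = 1, length.out = 10)
  expect_error(fit_population_smooth(daily_frame(dates, rnorm(10, 25)),
                                     "temperature"),
               "at least 20 distinct days")
  dates60 <- seq(as.Date("2015-05-01"), by = 1, length.out = 60)
  sm <- fit_population_smooth(daily_frame(dates60, rnorm(60, 25)),
                              "temperature")
  expect_error(predict(sm, 400), "training range")
})

test_that("a noisy seasonal curve is recovered within the noise envelope", {
  set.seed(7)
  n <- 2000
  d <- sample(seq(as.Date("2015-04-01"), as.Date("2015-09-15"), by = 1), n,
              replace = TRUE)
  truth <- 25 + 8 * sin((doy(d) - 91) / 168 * pi)
  noise_sd <- 1.2
  df <- daily_frame(d, truth + rnorm(n, 0, noise_sd))
  sm <- fit_population_smooth(df, "temperature")
  grid <- seq(min(doy(d)), max(doy(d)))
  truth_grid <- 25 + 8 * sin((grid - 91) / 168 * pi)
  rmse <- sqrt(mean((predict(sm, grid) - truth_grid)^2))
  expect_lt(rmse, 1.5 * noise_sd)
})

test_that("residual-sum index identities hold", {
  set.seed(8)
  dates <- seq(as.Date("2015-05-01"), by = 1, length.out = 80)
  pooled <- daily_frame(dates, 22 + 0.08 * seq_along(dates) + rnorm(80, 0, 0.5))
  sm <- fit_population_smooth(pooled, "temperature")
  window <- c(dates[1], dates[30])

  # a bird lying exactly on the fitted curve scores ~0
  on_curve <- daily_frame(dates[1:30], predict(sm, doy(dates[1:30])), "b")
  idx0 <- residual_sum_index(on_curve, sm, window)
  expect_equal(idx0$n_days, 30L)
  expect_lt(abs(idx0$index), 1e-8 * idx0$n_days)

  # +1 degree on every day moves the index by exactly n_days
  bird <- daily_frame(dates[1:30], 22 + rnorm(30), "c")
  base_idx <- residual_sum_index(bird, sm, window)
  shifted <- bird
  shifted$point_temp_C <- shifted$point_temp_C + 1
  shift_idx <- residual_sum_index(shifted, sm, window)
  expect_equal(shift_idx$index - base_idx$index, base_idx$n_days,
               tolerance = 1e-9)

  # additivity over disjoint windows
  w1 <- c(dates[1], dates[15]); w2 <- c(dates[16], dates[30])
  expect_equal(residual_sum_index(bird, sm, w1)$index +
                 residual_sum_index(bird, sm, w2)$index,
               base_idx$index, tolerance = 1e-9)

  # empty window: NA index with a message
  expect_message(
    empty <- residual_sum_index(bird, sm, c(dates[60], dates[70])),
    "no observed days")
  expect_true(is.na(empty$index))
})

test_that("training residuals of the population smooth sum to about zero", {
  set.seed(9)
  dates <- rep(seq(as.Date("2015-05-01"), by = 1, length.out = 70), 3)
  df <- daily_frame(dates, 24 + rnorm(210))
  sm <- fit_population_smooth(df, "temperature")
  res <- df$point_temp_C - predict(sm, doy(df$date))
  expect_lt(abs(sum(res)), 1e-6 * length(res))
})

test_that("exposure indices assemble per bird-season with a smooth per phase", {
  land <- test_landscape(seed = 61)
  sim <- simulate_tracks(land, n_birds = 6, n_residents = 0,
                         gps_noise_sd_m = 0, seed = 61)
  ev <- migration_events(sim$fixes)
  env <- suppressMessages(sample_environment(sim$fixes, land,
                                             skip_uncovered = TRUE))
  idx <- exposure_indices(daily_env(env), ev)
  expect_setequal(unique(idx$phase), c("breeding", "postbreeding"))
  expect_setequal(unique(idx$response), c("temperature", "ndvi"))
  expect_equal(nrow(idx), 6 * 4)
  sms <- attr(idx, "smooths")
  expect_named(sms, c("breeding.temperature", "breeding.ndvi",
                      "postbreeding.temperature", "postbreeding.ndvi"))
  # indices of a least-squares smooth roughly balance across the population
  tot <- sum(idx$index[idx$phase == "breeding" &
                         idx$response == "temperature"])
  n_days <- sum(idx$n_days[idx$phase == "breeding" &
                             idx$response == "temperature"])
  expect_lt(abs(tot) / n_days, 0.2)
})

test_that("smooths serialize to JSON with their fitted grid", {
  dates <- seq(as.Date("2015-05-01"), by = 1, length.out = 40)
  sm <- fit_population_smooth(daily_frame(dates, 20 + rnorm(40)),
                              "temperature")
  path <- withr::local_tempfile(fileext = ".json")
  write_smooth(sm, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$fitted, predict(sm, back$doy), tolerance = 1e-12)
  expect_equal(back$response, "temperature")
})
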