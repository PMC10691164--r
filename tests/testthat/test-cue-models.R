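test_that("collinearity screening flags duplicated and near-duplicated covariates", {
  set.seed(11)
  f <- tibble::tibble(x1 = rnorm(50), x3 = rnorm(50))
  f$x2 <- f$x1
  sc <- screen_collinearity(f, c("x1", "x2", "x3"))
  expect_true(any(sc$violations$type == "correlation" &
                    abs(sc$violations$value) >= 0.999))
  expect_true(is.infinite(sc$vif[["x1"]]))

  g <- tibble::tibble(x1 = rnorm(100), x3 = rnorm(100))
  g$x2 <- g$x1 + rnorm(100, 0, 0.05)
  sc2 <- screen_collinearity(g, c("x1", "x2", "x3"))
  expect_gt(sc2$vif[["x2"]], 3)
})

test_that("independent covariates pass the screen", {
  set.seed(12)
  f <- tibble::tibble(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  sc <- screen_collinearity(f, c("a", "b", "c"))
  expect_equal(nrow(sc$violations), 0)
  expect_true(all(sc$vif < 1.2))
})

test_that("AICc matches the closed-form hand computation", {
  set.seed(13)
  x <- rnorm(20); y <- 2 + 0.5 * x + rnorm(20)
  fit <- lm(y ~ x)  # k = 3: intercept, slope, sigma
  k <- 3; n <- 20
  expect_equal(aicc(fit), AIC(fit) + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-9)
  expect_equal(attr(logLik(fit), "df"), k)
  # undefined when n - k - 1 <= 0
  small <- lm(y[1:4] ~ x[1:4])
  expect_warning(out <- aicc(small), "undefined")
  expect_true(is.na(out))
})

test_that("term-set enumeration respects size caps and marginality", {
  terms <- c("a", "b", "c", "a:b")
  sets <- migcues:::enumerate_term_sets(terms)
  labels <- vapply(sets, paste, "", collapse = "+")
  expect_true("" %in% labels)              # null model
  expect_false(any(grepl("^a:b$", labels)))  # bare interaction dropped
  expect_true(any(vapply(sets, function(s) setequal(s, c("a", "b", "a:b")),
                         TRUE)))
  expect_equal(length(sets), 10)
  capped <- migcues:::enumerate_term_sets(c("a", "b", "c", "d"), max_terms = 3)
  expect_true(all(lengths(capped) <= 3))
})

test_that("selection tables rank by AICc with coherent weights and plausible set", {
  f <- simulate_model_frame(n_birds = 20, years = 2, seed = 14)
  sel <- suppressWarnings(select_models(f, "departure"))
  expect_equal(sel$delta_AICc[1], 0)
  expect_true(all(diff(sel$AICc) >= 0))
  expect_equal(sum(sel$weight), 1, tolerance = 1e-9)
  expect_true(sel$in_plausible_set[1])
  expect_true(all(sel$delta_AICc[sel$in_plausible_set] < 2))
  expect_true(inherits(attr(sel, "top_fit"), "merMod"))
})

test_that("covariate standardization does not change the AICc ranking", {
  f <- simulate_model_frame(n_birds = 20, years = 2, seed = 15)
  fz <- f
  for (v in c("refugia_pct", "rel_temp", "rel_ndvi")) {
    fz[[v]] <- as.numeric(scale(fz[[v]]))
  }
  a <- suppressWarnings(select_models(f, "departure"))
  b <- suppressWarnings(select_models(fz, "departure"))
  expect_identical(a$model, b$model)
  expect_equal(a$AICc, b$AICc, tolerance = 1e-5)
})

test_that("a simulated NDVI effect is recovered by the departure model", {
  f <- simulate_model_frame(n_birds = 30, years = 2,
                            beta = c(rel_ndvi = 8), resid_sd = 3, seed = 16)
  m <- fit_departure_model(f)
  td <- tidy(m)
  est <- td$estimate[td$term == "rel_ndvi"]
  expect_gt(est, 6.4); expect_lt(est, 9.6)
  expect_lt(td$p_value[td$term == "rel_ndvi"], 0.001)
  sel <- suppressWarnings(select_models(f, "departure"))
  expect_true(grepl("rel_ndvi", sel$model[1]))
})

test_that("an interaction shrinking the refugia effect at high temperature is recovered", {
  f <- simulate_model_frame(n_birds = 30, years = 2,
                            beta = c(refugia_pct = 4, rel_temp = 0,
                                     rel_ndvi = 8, refugia_x_temp = -3),
                            resid_sd = 1, seed = 17)
  m <- fit_departure_model(f)
  slopes <- marginal_refugia_slope(m, c(-1.5, 0, 1.5))
  expect_gt(slopes$refugia_slope[1], slopes$refugia_slope[3])
  expect_gt(slopes$refugia_slope[1], 0)
})

test_that("complete separation triggers the penalized fallback", {
  set.seed(18)
  f <- tibble::tibble(bird_id = sprintf("b%02d", 1:20),
                      rel_ndvi = c(rnorm(10, -2), rnorm(10, 2)))
  f$return_binary <- as.integer(f$rel_ndvi > 0)
  m <- fit_return_model(f, "rel_ndvi")
  expect_true(m$penalized)
  expect_true(all(is.finite(tidy(m)$estimate)))
  expect_lt(max(abs(lme4::fixef(m$fit))), 15)
})

test_that("return-model candidates cap at three terms", {
  f <- simulate_model_frame(n_birds = 16, years = 2, seed = 19)
  f <- f[!is.na(f$return_binary), ]
  expect_error(fit_return_model(f, c("rel_ndvi", "rel_temp", "refugia_pct",
                                     "rel_ndvi_post")),
               "at most 3")
  sel <- suppressWarnings(select_models(f, "return", max_terms = 3))
  expect_true(all(vapply(strsplit(sel$model, " \\+ "), function(s) {
    length(setdiff(s, "(null)")) <= 3
  }, TRUE)))
  expect_equal(sum(sel$weight), 1, tolerance = 1e-9)
})

test_that("spline correlograms detect constructed autocorrelation and respect seeds", {
  set.seed(20)
  n <- 40
  lon <- runif(n, -8.5, -6); lat <- runif(n, 37.5, 39.5)
  # iid residuals: envelope straddles zero nearly everywhere
  iid <- spline_correlogram(rnorm(n), lon, lat, n_boot = 100, seed = 21)
  expect_gt(mean(iid$lower <= 0 & iid$upper >= 0), 0.9)
  # latitude-driven residuals: strong positive short-range correlation
  res_grad <- 10 * lat + rnorm(n, 0, 0.1)
  grad <- spline_correlogram(res_grad, lon, lat, n_boot = 100, seed = 21)
  short <- grad$distance_km < quantile(grad$distance_km, 0.2)
  expect_gt(mean(grad$correlation[short]), 0.3)
  expect_true(all(grad$lower[short] > 0))
  # determinism
  again <- spline_correlogram(res_grad, lon, lat, n_boot = 100, seed = 21)
  expect_identical(grad$correlation, again$correlation)
  # degenerate input
  expect_error(spline_correlogram(rnorm(12), rep(1, 12), rep(38, 12)),
               "identical")
})
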