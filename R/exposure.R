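# Population-relative exposure indices: a penalized regression smooth of the
# pooled daily values against Julian date, and per-bird sums of residuals from
# that smooth over a phase window.

#' Fit the population seasonal smooth
#'
#' Pools all birds' day-averaged values and fits a Gaussian penalized cubic
#' regression spline of the value against day of year (basis dimension 10,
#' smoothing parameter by generalized cross-validation, via [mgcv::gam()]).
#' The fitted curve defines the population norm from which per-bird residual
#' sums are computed.
#'
#' @param daily A [daily_env()] table (or any data frame with `date` and the
#'   response column).
#' @param response "temperature" (uses `point_temp_C`) or "ndvi" (uses
#'   `ndvi`); or set `value_col` directly.
#' @param value_col Optional column name overriding `response`.
#' @param k Spline basis dimension (default 10).
#' @return A `population_smooth` object: the fitted [mgcv::gam()] model,
#'   response name, training day-of-year range and n.
#' @export
fit_population_smooth <- function(daily, response = c("temperature", "ndvi"),
                                  value_col = NULL, k = 10) {
  response <- match.arg(response)
  value_col <- value_col %||%
    switch(response, temperature = "point_temp_C", ndvi = "ndvi")
  stopifnot(value_col %in% names(daily), "date" %in% names(daily))
  df <- data.frame(doy = doy(daily$date), y = daily[[value_col]])
  df <- df[complete.cases(df), ]
  if (length(unique(df$doy)) < 20) {
    stop("need at least 20 distinct days to fit the population smooth; got ",
         length(unique(df$doy)))
  }
  if (sd(df$y) == 0) {
    warning("constant response; population smooth is flat at ", df$y[1])
  }
  kk <- min(k, max(3, length(unique(df$doy)) - 1))
  fit <- mgcv::gam(y ~ s(doy, k = kk, bs = "cr"), data = df,
                   method = "GCV.Cp")
  structure(list(model = fit, response = response, value_col = value_col,
                 doy_range = range(df$doy), n = nrow(df)),
            class = "population_smooth")
}

#' Evaluate a population smooth at days of year
#'
#' @param object A `population_smooth`.
#' @param doy Integer day(s) of year (1 Jan = 1); must lie in the training
#'   range.
#' @param ... Unused.
#' @return Fitted values.
#' @export
predict.population_smooth <- function(object, doy, ...) {
  if (any(doy < object$doy_range[1] | doy > object$doy_range[2])) {
    stop("day of year outside the smooth's training range [",
         object$doy_range[1], ", ", object$doy_range[2], "]")
  }
  as.numeric(predict(object$model, newdata = data.frame(doy = doy)))
}

#' @export
print.population_smooth <- function(x, ...) {
  cat("<population_smooth> ", x$response, "; n = ", x$n,
      "; days ", x$doy_range[1], "-", x$doy_range[2],
      "; edf = ", round(sum(x$model$edf), 2), "\n", sep = "")
  invisible(x)
}

#' @export
glance.population_smooth <- function(x, ...) {
  tibble::tibble(response = x$response, n = x$n,
                 edf = sum(x$model$edf),
                 gcv = as.numeric(x$model$gcv.ubre),
                 sigma = sqrt(x$model$sig2),
                 doy_min = x$doy_range[1], doy_max = x$doy_range[2])
}

#' Serialize a population smooth to JSON
#'
#' Every consumer of the smooth evaluates it at integer days of year, so the
#' smooth is stored as its fitted values on the integer-day training grid plus
#' the smoothing parameter; reading it back gives exact reuse for all package
#' purposes.
#'
#' @param smooth A `population_smooth`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_smooth <- function(smooth, path) {
  grid <- seq(smooth$doy_range[1], smooth$doy_range[2])
  jsonlite::write_json(
    list(response = smooth$response, n = smooth$n,
         sp = as.numeric(smooth$model$sp),
         doy = grid, fitted = predict(smooth, grid)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-bird residual-sum exposure index
#'
#' Sums the residuals of one bird's day-averaged values from the population
#' smooth over the observed days of a window: positive means the bird
#' experienced hotter (or greener) conditions than the population norm for
#' those dates. Missing days are simply absent from the sum.
#'
#' @param bird_daily [daily_env()] rows of one bird.
#' @param smooth The [fit_population_smooth()] result.
#' @param window Date vector c(start, end), inclusive.
#' @return One-row tibble: `index`, `n_days`. `index` is `NA` (with a
#'   message) when no observed days fall in the window.
#' @export
residual_sum_index <- function(bird_daily, smooth, window) {
  window <- as.Date(window)
  inw <- bird_daily$date >= window[1] & bird_daily$date <= window[2]
  d <- bird_daily[inw, , drop = FALSE]
  y <- d[[smooth$value_col]]
  ok <- !is.na(y)
  if (sum(ok) == 0) {
    message("no observed days in window ", format(window[1]), "..",
            format(window[2]), "; index is NA")
    return(tibble::tibble(index = NA_real_, n_days = 0L))
  }
  fitted <- predict(smooth, doy(d$date[ok]))
  tibble::tibble(index = sum(y[ok] - fitted), n_days = sum(ok))
}

#' Exposure indices for every migratory bird-season
#'
#' Fits one population smooth per response and phase on the pooled daily
#' values of that phase, then computes each bird-season's residual-sum index.
#' Windows follow the study conventions: breeding = season `breeding_start`
#' to the departure date; post-breeding = arrival (departure relocation day)
#' to `postbreeding_end`.
#'
#' @param daily [daily_env()] table for all birds.
#' @param events [migration_events()] table.
#' @param responses Character subset of c("temperature", "ndvi").
#' @param breeding_start,postbreeding_end Month-day strings.
#' @return Tibble: `bird_id`, `season_year`, `phase`, `response`, `index`,
#'   `n_days`; plus a `smooths` attribute holding the fitted population
#'   smooths, keyed `<phase>.<response>`.
#' @export
exposure_indices <- function(daily, events,
                             responses = c("temperature", "ndvi"),
                             breeding_start = "05-01",
                             postbreeding_end = "09-15") {
  mig <- events[events$strategy == "migrant", , drop = FALSE]
  if (nrow(mig) == 0) stop("no migratory bird-seasons")
  windows_of <- function(e, ph) {
    if (ph == "breeding") {
      c(as.Date(sprintf("%d-%s", e$season_year, breeding_start)),
        e$departure_date)
    } else {
      c(e$departure_date,
        as.Date(sprintf("%d-%s", e$season_year, postbreeding_end)))
    }
  }
  smooths <- list()
  out <- list()
  for (ph in c("breeding", "postbreeding")) {
    # pool all migrants' days falling in that phase across bird-seasons
    pool <- list()
    for (k in seq_len(nrow(mig))) {
      e <- mig[k, ]
      w <- windows_of(e, ph)
      if (w[2] < w[1]) next
      dd <- daily[daily$bird_id == e$bird_id &
                    daily$date >= w[1] & daily$date <= w[2], , drop = FALSE]
      pool[[length(pool) + 1]] <- dd
    }
    pooled <- dplyr::bind_rows(pool)
    for (resp in responses) {
      sm <- fit_population_smooth(pooled, resp)
      smooths[[paste(ph, resp, sep = ".")]] <- sm
      for (k in seq_len(nrow(mig))) {
        e <- mig[k, ]
        w <- windows_of(e, ph)
        if (w[2] < w[1]) next
        bd <- daily[daily$bird_id == e$bird_id, , drop = FALSE]
        idx <- residual_sum_index(bd, sm, w)
        out[[length(out) + 1]] <- tibble::tibble(
          bird_id = e$bird_id, season_year = e$season_year, phase = ph,
          response = resp, index = idx$index, n_days = idx$n_days)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "smooths") <- smooths
  res
}
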