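# Per-fix environmental extraction: hourly cell temperature, 500 m buffer
# minimum/median, the cool-microrefugium indicator, and nearest-composite
# NDVI; plus day-level averaging and per-season summaries.

#' Microrefugium indicator
#'
#' TRUE when the buffer minimum is at least `threshold_C` cooler than the
#' buffer median (inclusive threshold): the location offers a cool
#' microclimate refugium.
#'
#' @param buffer_min_C,buffer_median_C Buffer statistics in degrees C.
#' @param threshold_C Cooling threshold (default 0.5).
#' @return Logical vector.
#' @export
#' @examples
#' refugia_indicator(29.5, 30.0) # TRUE: exactly 0.5 cooler counts
refugia_indicator <- function(buffer_min_C, buffer_median_C,
                              threshold_C = 0.5) {
  stopifnot(is.finite(buffer_min_C), is.finite(buffer_median_C))
  if (any(buffer_min_C > buffer_median_C + 1e-12)) {
    stop("buffer_min_C exceeds buffer_median_C; upstream extraction bug")
  }
  (buffer_median_C - buffer_min_C) >= threshold_C
}

#' NDVI from reflectance
#'
#' Normalized difference vegetation index, (NIR - Red) / (NIR + Red).
#'
#' @param nir,red Non-negative reflectance values.
#' @return NDVI in `[-1, 1]`; `NA` with a warning where `nir + red == 0`.
#' @export
#' @examples
#' ndvi_from_reflectance(0.4, 0.1) # 0.6
ndvi_from_reflectance <- function(nir, red) {
  stopifnot(all(nir >= 0), all(red >= 0))
  s <- nir + red
  out <- ifelse(s == 0, NA_real_, (nir - red) / s)
  if (anyNA(out)) warning("NDVI undefined where nir + red == 0; returned NA")
  out
}

#' Match fixes to the nearest NDVI composite
#'
#' @param fixes Fix table with `lon`, `lat`, `timestamp`.
#' @param landscape A `migcues_landscape`.
#' @return NDVI of the composite nearest each fix date (ties to the earlier
#'   composite), at the cell containing the fix.
#' @export
match_ndvi <- function(fixes, landscape) {
  ndvi_at(landscape, fixes$lon, fixes$lat,
          as.Date(fixes$timestamp, tz = "UTC"))
}

#' Sample temperature and NDVI at GPS fixes
#'
#' For each fix: the temperature of the containing cell at the nearest hour;
#' the minimum and median temperature over cells whose centres lie within
#' `buffer_m` (geodesic) of the fix; the microrefugium flag
#' ([refugia_indicator()]); and nearest-composite NDVI. Fixes whose buffer is
#' truncated by the grid edge are kept but flagged `buffer_complete = FALSE`
#' and excluded from refugia percentages downstream. The median uses the
#' conventional midpoint rule for even cell counts.
#'
#' @param fixes Fix table (`bird_id`, `timestamp`, `lon`, `lat`).
#' @param landscape A `migcues_landscape`.
#' @param buffer_m Buffer radius in metres (default 500).
#' @param refugia_threshold_C Cooling threshold (default 0.5).
#' @param skip_uncovered Drop (with a message) fixes dated outside the
#'   landscape's temperature series instead of erroring.
#' @return Tibble: fix columns plus `point_temp_C`, `buffer_min_C`,
#'   `buffer_median_C`, `refugia_flag`, `ndvi`, `buffer_complete`.
#' @export
sample_environment <- function(fixes, landscape, buffer_m = 500,
                               refugia_threshold_C = 0.5,
                               skip_uncovered = FALSE) {
  cfg <- landscape$config
  ts <- as.POSIXct(fixes$timestamp, tz = "UTC")
  dates <- as.Date(ts, tz = "UTC")
  covered <- date_covered(cfg, dates)
  if (!all(covered)) {
    if (!skip_uncovered) {
      stop(sum(!covered), " fixes dated outside the temperature series (",
           format(cfg$season_start), " to ", format(cfg$season_end), ")")
    }
    message(sum(!covered), " fixes outside temperature coverage dropped")
    fixes <- fixes[covered, , drop = FALSE]
    ts <- ts[covered]
  }
  n <- nrow(fixes)
  hr <- nearest_hour(ts)
  base <- base_temperature(landscape, hr$date, hr$hour)
  idx <- cell_index(landscape, fixes$lon, fixes$lat)
  point <- base + landscape$anomaly[cbind(idx$row, idx$col)]

  bmin <- bmed <- numeric(n)
  complete <- logical(n)
  for (i in seq_len(n)) {
    cells <- buffer_cells(landscape, fixes$lon[i], fixes$lat[i], buffer_m)
    a <- landscape$anomaly[cbind(cells$row, cells$col)]
    bmin[i] <- base[i] + min(a)
    bmed[i] <- base[i] + median(a)
    complete[i] <- attr(cells, "complete")
  }
  tibble::as_tibble(fixes) |>
    dplyr::mutate(point_temp_C = point,
                  buffer_min_C = bmin,
                  buffer_median_C = bmed,
                  refugia_flag = refugia_indicator(bmin, bmed,
                                                   refugia_threshold_C),
                  ndvi = match_ndvi(fixes, landscape),
                  buffer_complete = complete)
}

#' Day-averaged environmental values
#'
#' Averages each bird's environmental samples by UTC day; temperature
#' variables and NDVI are day-averaged, the per-fix refugium flags are not
#' (refugia availability is summarised over fixes, see [summarize_season()]).
#'
#' @param env_samples Result of [sample_environment()].
#' @return Tibble: `bird_id`, `date`, `point_temp_C`, `buffer_min_C`,
#'   `buffer_median_C`, `ndvi`, `n_samples`.
#' @export
daily_env <- function(env_samples) {
  env_samples |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::summarise(point_temp_C = mean(.data$point_temp_C),
                     buffer_min_C = mean(.data$buffer_min_C),
                     buffer_median_C = mean(.data$buffer_median_C),
                     ndvi = mean(.data$ndvi),
                     n_samples = dplyr::n(),
                     .by = c("bird_id", "date")) |>
    dplyr::arrange(.data$bird_id, .data$date)
}

#' Seasonal refugia availability summary
#'
#' Percentage of a bird's GPS fixes in a window that had an available
#' microrefugium. The default basis is per fix on hourly values; the
#' `"daily"` basis instead flags day-averaged buffer statistics and computes
#' the percentage over days.
#'
#' @param env_samples Samples of one bird ([sample_environment()]).
#' @param window Date vector c(start, end), inclusive.
#' @param phase Label, e.g. "breeding" or "postbreeding".
#' @param refugia_threshold_C Cooling threshold (default 0.5).
#' @param basis "fix" (default) or "daily".
#' @return One-row tibble: `phase`, `window_start`, `window_end`,
#'   `refugia_pct`, `n_fixes` (or days). Errors if the window holds no valid
#'   samples.
#' @export
summarize_season <- function(env_samples, window, phase = "breeding",
                             refugia_threshold_C = 0.5,
                             basis = c("fix", "daily")) {
  basis <- match.arg(basis)
  window <- as.Date(window)
  d <- as.Date(env_samples$timestamp, tz = "UTC")
  keep <- d >= window[1] & d <= window[2] & env_samples$buffer_complete
  s <- env_samples[keep, , drop = FALSE]
  if (nrow(s) == 0) stop("empty_window: no valid samples in ",
                         format(window[1]), "..", format(window[2]))
  if (basis == "fix") {
    pct <- 100 * mean(s$refugia_flag)
    n <- nrow(s)
  } else {
    day <- daily_env(s)
    flag <- refugia_indicator(day$buffer_min_C, day$buffer_median_C,
                              refugia_threshold_C)
    pct <- 100 * mean(flag)
    n <- nrow(day)
  }
  tibble::tibble(phase = phase, window_start = window[1],
                 window_end = window[2], refugia_pct = pct, n_fixes = n)
}

#' Per-event seasonal environmental summaries
#'
#' For each migratory bird-season, summarises refugia availability over the
#' breeding window (season `breeding_start` to the departure date) and the
#' post-breeding window (arrival, i.e. the departure relocation day, to
#' `postbreeding_end`).
#'
#' @param env_samples Samples for all birds ([sample_environment()]).
#' @param events Migration events ([migration_events()]).
#' @param breeding_start,postbreeding_end Month-day strings (defaults
#'   "05-01" and "09-15").
#' @inheritParams summarize_season
#' @return Tibble: `bird_id`, `season_year`, `phase`, window, `refugia_pct`,
#'   `n_fixes`; bird-seasons with an empty window are dropped with a message.
#' @export
season_env_summaries <- function(env_samples, events,
                                 breeding_start = "05-01",
                                 postbreeding_end = "09-15",
                                 refugia_threshold_C = 0.5,
                                 basis = c("fix", "daily")) {
  basis <- match.arg(basis)
  mig <- events[events$strategy == "migrant", , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(mig))) {
    e <- mig[k, ]
    s <- env_samples[env_samples$bird_id == e$bird_id, , drop = FALSE]
    windows <- list(
      breeding = c(as.Date(sprintf("%d-%s", e$season_year, breeding_start)),
                   e$departure_date),
      postbreeding = c(e$departure_date,
                       as.Date(sprintf("%d-%s", e$season_year,
                                       postbreeding_end))))
    for (ph in names(windows)) {
      w <- windows[[ph]]
      if (w[2] < w[1]) next
      row <- tryCatch(
        summarize_season(s, w, ph, refugia_threshold_C, basis),
        error = function(err) NULL)
      if (is.null(row)) {
        message("no valid samples for ", e$bird_id, " ", e$season_year,
                " ", ph, "; dropped")
        next
      }
      out[[length(out) + 1]] <- dplyr::bind_cols(
        tibble::tibble(bird_id = e$bird_id, season_year = e$season_year), row)
    }
  }
  dplyr::bind_rows(out)
}
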