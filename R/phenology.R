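# Trajectory phenology: daily centroids, breeding reference centroid,
# departure/return detection with a sustained-period rule, residency
# classification, and migration distance metrics.

#' Daily centroids of GPS fixes
#'
#' Arithmetic mean position of each bird's fixes per UTC day. Duplicate
#' (bird, timestamp) rows are dropped with a warning; days with no fixes are
#' simply absent.
#'
#' @param fixes Data frame with columns `bird_id`, `timestamp` (POSIXct or
#'   ISO-8601 string, UTC), `lon`, `lat`.
#' @return Tibble: `bird_id`, `date`, `lon`, `lat`, `n_fixes`.
#' @export
#' @examples
#' fx <- tibble::tibble(bird_id = "a",
#'   timestamp = as.POSIXct("2015-05-01 00:00", tz = "UTC") + c(0, 3600),
#'   lon = c(0, 0.02), lat = 38)
#' daily_centroids(fx)
daily_centroids <- function(fixes) {
  stopifnot(all(c("bird_id", "timestamp", "lon", "lat") %in% names(fixes)))
  ts <- fixes$timestamp
  if (!inherits(ts, "POSIXct")) {
    parsed <- as.POSIXct(rep(NA_real_, length(ts)), origin = "1970-01-01",
                         tz = "UTC")
    for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
      miss <- is.na(parsed)
      if (!any(miss)) break
      parsed[miss] <- as.POSIXct(strptime(ts[miss], fmt, tz = "UTC"))
    }
    if (anyNA(parsed)) {
      stop("unparseable timestamp at row ",
           paste(head(which(is.na(parsed)), 5), collapse = ", "))
    }
    fixes$timestamp <- parsed
  }
  if (any(abs(fixes$lat) > 90) || any(abs(fixes$lon) > 180)) {
    stop("coordinates outside WGS84 bounds")
  }
  dup <- duplicated(fixes[c("bird_id", "timestamp")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (bird_id, timestamp) fixes dropped")
    fixes <- fixes[!dup, ]
  }
  fixes |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::summarise(lon = mean(.data$lon), lat = mean(.data$lat),
                     n_fixes = dplyr::n(),
                     .by = c("bird_id", "date")) |>
    dplyr::arrange(.data$bird_id, .data$date)
}

# Breeding season-year of a date: seasons run 1 April to 31 March, so
# winter returns stay attached to the breeding season they follow.
season_year_of <- function(date) {
  d <- as.Date(date)
  y <- as.integer(format(d, "%Y"))
  ifelse(as.integer(format(d, "%m")) >= 4, y, y - 1L)
}

#' Breeding reference centroid
#'
#' Mean of the daily centroids inside a window; the spatial reference against
#' which departure and return are measured. Bird-seasons with fewer than
#' `min_days` centroid days in the window are ineligible.
#'
#' @param centroids Daily centroids of one bird-season ([daily_centroids()]).
#' @param window Date vector c(start, end), inclusive.
#' @param min_days Minimum distinct centroid days required (default 7).
#' @param method "mean" (the reference definition) or "median"
#'   (componentwise; used for the provisional first pass, where the window may
#'   still contain post-departure days that would drag a mean).
#' @return A list: `lon`, `lat`, `n_days`, `window`; or an error if
#'   ineligible.
#' @export
breeding_reference <- function(centroids, window, min_days = 7L,
                               method = c("mean", "median")) {
  method <- match.arg(method)
  window <- as.Date(window)
  inw <- centroids$date >= window[1] & centroids$date <= window[2]
  n <- length(unique(centroids$date[inw]))
  if (n < min_days) {
    stop("insufficient_predeparture_days: only ", n,
         " centroid days in the reference window (need ", min_days, ")")
  }
  agg <- if (method == "mean") mean else median
  list(lon = agg(centroids$lon[inw]), lat = agg(centroids$lat[inw]),
       n_days = n, window = window)
}

# Distance (km) of each centroid day from the reference.
centroid_dist_km <- function(centroids, reference) {
  geo_dist_km(centroids$lon, centroids$lat, reference$lon, reference$lat)
}

# Split an ordered logical state sequence over observed dates into runs.
# A run continues across an unobserved gap of at most max_gap_days missing
# calendar days; a longer gap breaks it. Returns per-run first/last date and
# whether the run reaches the last observed date.
state_runs <- function(dates, state, max_gap_days = 3L) {
  keep <- which(state)
  if (length(keep) == 0) return(NULL)
  d <- dates[keep]
  # A new run starts when the previous state-date is separated by a non-state
  # observed date or by too long an unobserved gap.
  brk <- logical(length(d))
  if (length(d) > 1) {
    for (i in 2:length(d)) {
      gap_days <- as.integer(d[i] - d[i - 1]) - 1L
      # an observed date strictly between two consecutive state dates is
      # necessarily an opposite-state day and breaks the run
      opposite <- any(dates > d[i - 1] & dates < d[i])
      brk[i] <- opposite || gap_days > max_gap_days
    }
  }
  ids <- cumsum(c(TRUE, brk[-1]))
  run_id <- factor(ids, levels = unique(ids))
  last_obs <- max(dates)
  out <- data.frame(
    start = as.Date(as.vector(tapply(as.numeric(d), run_id, min)),
                    origin = "1970-01-01"),
    end = as.Date(as.vector(tapply(as.numeric(d), run_id, max)),
                  origin = "1970-01-01"))
  out$span_days <- as.integer(out$end - out$start) + 1L
  out$reaches_track_end <- out$end == last_obs
  out
}

#' Detect departure from the breeding area
#'
#' Departure is the first date from which the bird's daily centroid stays more
#' than `radius_km` from the breeding reference for at least `min_away_days`
#' consecutive days. Unobserved gaps of at most `max_gap_days` inside an
#' away-run count toward the period; longer gaps break it. A bird with no
#' qualifying run is a resident; if tracking ends while an unconfirmed run is
#' open, the bird-season is censored.
#'
#' @param centroids Daily centroids of one bird-season.
#' @param reference A [breeding_reference()].
#' @param radius_km In/out threshold in km (default 1.5, the residency
#'   criterion).
#' @param min_away_days Minimum sustained period (default 30, one month).
#' @param max_gap_days Longest unobserved gap bridged inside a run (default 3).
#' @return List: `status` ("migrant", "resident" or "censored") and
#'   `departure_date` (NA unless migrant).
#' @export
detect_departure <- function(centroids, reference, radius_km = 1.5,
                             min_away_days = 30L, max_gap_days = 3L) {
  dist <- centroid_dist_km(centroids, reference)
  runs <- state_runs(centroids$date, dist > radius_km, max_gap_days)
  if (is.null(runs)) return(list(status = "resident",
                                 departure_date = as.Date(NA)))
  ok <- runs$span_days >= min_away_days
  if (any(ok)) {
    return(list(status = "migrant", departure_date = runs$start[which(ok)[1]]))
  }
  open <- runs$reaches_track_end
  if (any(open)) {
    # track ended while the bird was away but before the one-month rule could
    # be confirmed
    return(list(status = "censored", departure_date = as.Date(NA)))
  }
  list(status = "resident", departure_date = as.Date(NA))
}

#' Detect return to the breeding area
#'
#' First date after departure at which the centroid is back within
#' `radius_km` of the breeding reference, sustained for `min_back_days`.
#' Censored (with reason `"track_ended"`) if tracking ends away or during an
#' unconfirmed home-run.
#'
#' @inheritParams detect_departure
#' @param departure Departure date.
#' @param min_back_days Days the bird must stay back (default 7).
#' @return List: `return_date` (NA if censored) and `censoring_reason`
#'   ("none" or "track_ended").
#' @export
detect_return <- function(centroids, reference, departure, radius_km = 1.5,
                          min_back_days = 7L, max_gap_days = 3L) {
  post <- centroids[centroids$date > as.Date(departure), , drop = FALSE]
  if (nrow(post) == 0) {
    return(list(return_date = as.Date(NA), censoring_reason = "track_ended"))
  }
  dist <- centroid_dist_km(post, reference)
  runs <- state_runs(post$date, dist <= radius_km, max_gap_days)
  if (!is.null(runs)) {
    ok <- runs$span_days >= min_back_days
    if (any(ok)) {
      return(list(return_date = runs$start[which(ok)[1]],
                  censoring_reason = "none"))
    }
    if (any(runs$reaches_track_end)) {
      return(list(return_date = as.Date(NA), censoring_reason = "track_ended"))
    }
  }
  list(return_date = as.Date(NA), censoring_reason = "track_ended")
}

#' Migration distance metrics
#'
#' Two summaries of how far a migrant moved: the cumulative sum over observed
#' post-breeding days of the geodesic distance between the breeding reference
#' and that day's centroid (`distance_cumulative_km`), and the distance from
#' the reference to the mean post-breeding centroid (`distance_site_km`). The
#' cumulative sum grows with tracking duration, so the site distance is the
#' default scalar for between-year comparisons.
#'
#' @param centroids Daily centroids of one bird-season.
#' @param reference A [breeding_reference()].
#' @param departure Departure date.
#' @param end_date Last post-breeding date (exclusive upper bound is not
#'   applied; days in `[departure, end_date]` count). Typically the day before
#'   return, or the last tracked day.
#' @return List: `distance_cumulative_km`, `distance_site_km`, `n_days`.
#' @export
migration_distance <- function(centroids, reference, departure, end_date) {
  if (is.na(departure)) stop("migration_distance requires a departure date")
  post <- centroids[centroids$date >= as.Date(departure) &
                      centroids$date <= as.Date(end_date), , drop = FALSE]
  if (nrow(post) == 0) stop("no post-breeding centroid days")
  d <- centroid_dist_km(post, reference)
  list(distance_cumulative_km = sum(d),
       distance_site_km = geo_dist_km(mean(post$lon), mean(post$lat),
                                      reference$lon, reference$lat),
       n_days = nrow(post))
}

#' Migration events from raw fixes
#'
#' End-to-end phenology for every bird-season: daily centroids, a two-pass
#' breeding reference (provisional median over the capture window, then the
#' mean over capture-to-departure iterated to stability), departure and return
#' detection, residency
#' classification, and distance metrics. Bird-seasons whose first fix falls
#' after the breeding-season start, or with fewer than `min_predeparture_days`
#' centroid days before departure, are excluded with a reason.
#'
#' @param fixes Fix table (see [daily_centroids()]).
#' @param radius_km,min_away_days,min_back_days,max_gap_days Detection rules;
#'   see [detect_departure()] and [detect_return()].
#' @param min_predeparture_days Minimum centroid days before departure
#'   (default 7).
#' @param capture_deadline Month-day ("MM-DD") by which tracking must have
#'   started (default "05-01"); later starts are excluded.
#' @return Tibble with one row per retained bird-season: `bird_id`,
#'   `season_year`, `strategy`, `departure_date`, `return_date`,
#'   `censoring_reason`, `distance_cumulative_km`, `distance_site_km`,
#'   `breeding_lon`, `breeding_lat`, `n_predeparture_days`. Excluded
#'   bird-seasons are recorded in the `exclusions` attribute (see
#'   [phenology_exclusions()]).
#' @export
migration_events <- function(fixes, radius_km = 1.5, min_away_days = 30L,
                             min_back_days = 7L, max_gap_days = 3L,
                             min_predeparture_days = 7L,
                             capture_deadline = "05-01") {
  cents <- daily_centroids(fixes)
  cents$season_year <- season_year_of(cents$date)
  combos <- dplyr::distinct(cents, .data$bird_id, .data$season_year)
  # seasons that only contain post-new-year carryover (Jan-Mar of a season
  # whose April-December the bird was not tracked) are not bird-seasons
  rows <- list(); excl <- list()
  for (k in seq_len(nrow(combos))) {
    bid <- combos$bird_id[k]; sy <- combos$season_year[k]
    cc <- cents[cents$bird_id == bid & cents$season_year == sy, , drop = FALSE]
    first_day <- min(cc$date)
    if (format(first_day, "%m-%d") > capture_deadline ||
        first_day >= as.Date(sprintf("%d-09-01", sy))) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        bird_id = bid, season_year = sy, reason = "capture_after_season_start")
      next
    }
    # pass 1: provisional reference from the capture window -- the first
    # min_predeparture_days observed days, componentwise median. Birds are
    # captured at the breeding area and every retained bird-season has at
    # least that many pre-departure days, so this window is pre-departure by
    # construction; the median tolerates a minority of early away-days. The
    # mean reference over capture -> departure is then iterated until the
    # detected departure is stable (one step on clean tracks).
    obs_days <- sort(unique(cc$date))
    if (length(obs_days) < min_predeparture_days) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        bird_id = bid, season_year = sy,
        reason = "insufficient_predeparture_days")
      next
    }
    capture_end <- obs_days[min_predeparture_days]
    ref <- breeding_reference(cc, c(first_day, capture_end),
                              min_days = min_predeparture_days,
                              method = "median")
    dep <- detect_departure(cc, ref, radius_km, min_away_days, max_gap_days)
    for (pass in 1:3) {
      ref_end <- if (dep$status == "migrant") dep$departure_date - 1 else
        max(cc$date)
      ref2 <- tryCatch(breeding_reference(cc, c(first_day, ref_end),
                                          min_days = min_predeparture_days),
                       error = function(e) NULL)
      if (is.null(ref2)) break
      dep2 <- detect_departure(cc, ref2, radius_km, min_away_days, max_gap_days)
      stable <- identical(dep2$status, dep$status) &&
        identical(dep2$departure_date, dep$departure_date)
      ref <- ref2; dep <- dep2
      if (stable) break
    }
    if (is.null(ref2)) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        bird_id = bid, season_year = sy,
        reason = "insufficient_predeparture_days")
      next
    }
    if (dep$status == "censored") {
      excl[[length(excl) + 1]] <- tibble::tibble(
        bird_id = bid, season_year = sy, reason = "track_ended_before_one_month")
      next
    }
    if (dep$status == "resident" &&
        max(cc$date) < as.Date(sprintf("%d-09-01", sy))) {
      # cannot distinguish residency from an unobserved later departure when
      # the track does not cover the season
      excl[[length(excl) + 1]] <- tibble::tibble(
        bird_id = bid, season_year = sy,
        reason = "insufficient_season_coverage")
      next
    }
    if (dep$status == "resident") {
      rows[[length(rows) + 1]] <- tibble::tibble(
        bird_id = bid, season_year = sy, strategy = "resident",
        departure_date = as.Date(NA), return_date = as.Date(NA),
        censoring_reason = "resident",
        distance_cumulative_km = NA_real_, distance_site_km = NA_real_,
        breeding_lon = ref$lon, breeding_lat = ref$lat,
        n_predeparture_days = ref$n_days)
      next
    }
    ret <- detect_return(cc, ref, dep$departure_date, radius_km,
                         min_back_days, max_gap_days)
    dist_end <- if (!is.na(ret$return_date)) ret$return_date - 1 else
      max(cc$date)
    md <- migration_distance(cc, ref, dep$departure_date, dist_end)
    rows[[length(rows) + 1]] <- tibble::tibble(
      bird_id = bid, season_year = sy, strategy = "migrant",
      departure_date = dep$departure_date, return_date = ret$return_date,
      censoring_reason = ret$censoring_reason,
      distance_cumulative_km = md$distance_cumulative_km,
      distance_site_km = md$distance_site_km,
      breeding_lon = ref$lon, breeding_lat = ref$lat,
      n_predeparture_days = ref$n_days)
  }
  events <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  attr(events, "exclusions") <- if (length(excl)) dplyr::bind_rows(excl) else
    tibble::tibble(bird_id = character(), season_year = integer(),
                   reason = character())
  events
}

#' Exclusion log of a migration-event table
#'
#' @param events Result of [migration_events()].
#' @return Tibble: `bird_id`, `season_year`, `reason`.
#' @export
phenology_exclusions <- function(events) {
  attr(events, "exclusions") %||%
    tibble::tibble(bird_id = character(), season_year = integer(),
                   reason = character())
}
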