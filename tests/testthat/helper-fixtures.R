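# Shared fixtures, built in code.

# Default-sized landscape for unit tests (the 100 x 100 default leaves room
# for bird placement margins).
test_landscape <- function(seed = 11, ...) {
  simulate_landscape(landscape_config(seed = seed, ...))
}

# Hand-built fix table: one bird sitting at `site` from `from` to `to`
# (2 fixes/day), optionally relocated to `away_site` during [departure, back).
manual_fixes <- function(bird_id = "b1", site = c(-7.0, 38.5),
                         from, to, departure = NULL, back = NULL,
                         away_site = NULL) {
  days <- seq(as.Date(from), as.Date(to), by = 1)
  away <- rep(FALSE, length(days))
  if (!is.null(departure)) {
    away <- days >= as.Date(departure) &
      (if (is.null(back)) TRUE else days < as.Date(back))
  }
  lon <- ifelse(away, away_site[1], site[1])
  lat <- ifelse(away, away_site[2], site[2])
  tibble::tibble(
    bird_id = bird_id,
    timestamp = as.POSIXct(rep(days, each = 2), tz = "UTC") +
      rep(c(8, 16) * 3600, length(days)),
    lon = rep(lon, each = 2), lat = rep(lat, each = 2))
}

# Exhaustive buffer oracle: enumerates every grid cell, geodesic distance from
# the fix to each cell centre, and takes min / midpoint-median of the included
# temperatures. Independent of the package's windowed search.
brute_force_buffer <- function(landscape, lon, lat, date, hour,
                               radius_m = 500) {
  nr <- length(landscape$cell_lat); nc <- length(landscape$cell_lon)
  vals <- c()
  base <- base_temperature(landscape, date, hour)
  for (r in seq_len(nr)) {
    d <- geosphere::distGeo(c(lon, lat),
                            cbind(landscape$cell_lon, landscape$cell_lat[r]))
    inside <- which(d <= radius_m)
    if (length(inside)) {
      vals <- c(vals, base + landscape$anomaly[r, inside])
    }
  }
  s <- sort(vals)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  list(min = s[1], median = med, n = n)
}
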