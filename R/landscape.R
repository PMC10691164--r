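# Synthetic landscape: hourly near-ground temperature with cool microrefugia
# patches, plus 8-day NDVI composites. The grid is stored as matrices with an
# explicit geotransform (origin + cell size); temperature separates into a
# static spatial anomaly (refugia cooling + cell noise) and a diel/seasonal
# base curve, so any hour is reconstructed exactly without storing 4000 layers.

#' Configuration for a synthetic microclimate landscape
#'
#' Defines a rectangular grid of square cells (WGS84 origin, metric cell size)
#' with patchy cool microrefugia, a diel + seasonal temperature cycle, and a
#' spring-peaking NDVI field that senesces linearly after its peak.
#'
#' @param grid_shape Integer c(rows, cols); at least 20 x 20 so a 500 m buffer
#'   fits inside the grid at 30 m cells.
#' @param cell_size_m Cell edge length in metres (default 30).
#' @param origin_lon,origin_lat South-west corner of the grid, decimal degrees.
#' @param n_refugia_patches Number of 3 x 3 cool patches.
#' @param refugia_cooling_C Temperature depression of patch cells in degrees C
#'   (> 0); before noise, patch cells sit exactly this far below the non-patch
#'   level.
#' @param base_diel_cycle Named or unnamed c(min, max) degrees C of the diel
#'   cycle at season start (daily minimum near 02:00, maximum near 14:00).
#' @param seasonal_trend_C_per_day Linear warming per day across the season.
#' @param noise_sd_C SD of static per-cell temperature noise (>= 0).
#' @param ndvi_peak_day Day of year at which NDVI peaks (plateau before).
#' @param ndvi_senescence_rate Fractional NDVI decline per day after the peak;
#'   0 gives a season-constant field.
#' @param year Calendar year of the simulated season.
#' @param season_start,season_end Dates bounding the temperature series
#'   (defaults 1 April and 15 September of `year`).
#' @param wrap Treat the landscape as spatially periodic (default TRUE):
#'   points outside the grid are translated back into it modulo the grid
#'   extent, so distant post-breeding sites sample a statistically identical
#'   environment. With `wrap = FALSE` such points are an error.
#' @param seed RNG seed; identical config + seed gives bit-identical output.
#' @return A `landscape_config` list.
#' @seealso [simulate_landscape()]
#' @export
landscape_config <- function(grid_shape = c(100L, 100L),
                             cell_size_m = 30,
                             origin_lon = -7.0,
                             origin_lat = 38.5,
                             n_refugia_patches = 12L,
                             refugia_cooling_C = 1.0,
                             base_diel_cycle = c(min = 18, max = 36),
                             seasonal_trend_C_per_day = 0.05,
                             noise_sd_C = 0.1,
                             ndvi_peak_day = 120L,
                             ndvi_senescence_rate = 0.006,
                             year = 2015L,
                             season_start = NULL,
                             season_end = NULL,
                             wrap = TRUE,
                             seed = 1L) {
  stopifnot(length(grid_shape) == 2, refugia_cooling_C > 0, noise_sd_C >= 0,
            cell_size_m > 0, length(base_diel_cycle) == 2,
            base_diel_cycle[2] >= base_diel_cycle[1],
            ndvi_senescence_rate >= 0)
  cfg <- list(
    grid_shape = as.integer(grid_shape),
    cell_size_m = cell_size_m,
    origin_lon = origin_lon, origin_lat = origin_lat,
    n_refugia_patches = as.integer(n_refugia_patches),
    refugia_cooling_C = refugia_cooling_C,
    base_diel_cycle = unname(base_diel_cycle),
    seasonal_trend_C_per_day = seasonal_trend_C_per_day,
    noise_sd_C = noise_sd_C,
    ndvi_peak_day = as.integer(ndvi_peak_day),
    ndvi_senescence_rate = ndvi_senescence_rate,
    year = as.integer(year),
    season_start = as.Date(season_start %||% sprintf("%d-04-01", year)),
    season_end = as.Date(season_end %||% sprintf("%d-09-15", year)),
    wrap = isTRUE(wrap),
    seed = as.integer(seed)
  )
  structure(cfg, class = "landscape_config")
}

#' Generate a synthetic landscape
#'
#' Builds the temperature anomaly field (cool microrefugia patches plus static
#' cell noise), the NDVI greenness field, the cell-centre geometry and the
#' 8-day composite calendar from a [landscape_config()]. Before noise, every
#' refugia patch cell is exactly `refugia_cooling_C` below the non-patch level
#' at every hour; the patch truth mask is carried in the result.
#'
#' @param config A [landscape_config()].
#' @return A `migcues_landscape` object: config, `cell_lon`/`cell_lat`
#'   (cell-centre coordinate vectors; row 1 is the southernmost row),
#'   `anomaly` (rows x cols static temperature anomaly, degrees C),
#'   `refugia_mask` (logical truth mask), `greenness` (peak NDVI per cell),
#'   and `composite_dates` (8-day NDVI composite calendar).
#' @export
#' @examples
#' land <- simulate_landscape(landscape_config(seed = 7))
#' mean(land$refugia_mask)
simulate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  if (nr < 20 || nc < 20) {
    stop("grid_shape must be at least 20 x 20 so a 500 m buffer fits; got ",
         nr, " x ", nc)
  }
  set.seed(config$seed)

  # Cell-centre geometry: metric spacing converted to degrees at the origin.
  m_per_deg_lat <- geosphere::distGeo(c(config$origin_lon, config$origin_lat),
                                      c(config$origin_lon, config$origin_lat + 1))
  m_per_deg_lon <- geosphere::distGeo(c(config$origin_lon, config$origin_lat),
                                      c(config$origin_lon + 1, config$origin_lat))
  cell_lat <- config$origin_lat +
    (seq_len(nr) - 0.5) * config$cell_size_m / m_per_deg_lat
  cell_lon <- config$origin_lon +
    (seq_len(nc) - 0.5) * config$cell_size_m / m_per_deg_lon

  # Refugia patches: 3 x 3 blocks around interior centres.
  mask <- matrix(FALSE, nr, nc)
  if (config$n_refugia_patches > 0) {
    cr <- sample(2:(nr - 1), config$n_refugia_patches, replace = TRUE)
    cc <- sample(2:(nc - 1), config$n_refugia_patches, replace = TRUE)
    for (p in seq_len(config$n_refugia_patches)) {
      mask[(cr[p] - 1):(cr[p] + 1), (cc[p] - 1):(cc[p] + 1)] <- TRUE
    }
  }
  anomaly <- -config$refugia_cooling_C * mask
  if (config$noise_sd_C > 0) {
    anomaly <- anomaly + matrix(rnorm(nr * nc, 0, config$noise_sd_C), nr, nc)
  }

  # Greenness: box-smoothed uniform field rescaled into [0.2, 0.9].
  raw <- matrix(runif(nr * nc), nr, nc)
  sm <- box_smooth(raw, 2)
  rng <- range(sm)
  greenness <- if (diff(rng) > 0) 0.2 + 0.7 * (sm - rng[1]) / diff(rng)
               else matrix(0.55, nr, nc)

  composite_dates <- seq(config$season_start, config$season_end, by = 8)

  structure(list(config = config,
                 cell_lon = cell_lon, cell_lat = cell_lat,
                 m_per_deg_lat = m_per_deg_lat, m_per_deg_lon = m_per_deg_lon,
                 anomaly = anomaly, refugia_mask = mask,
                 greenness = greenness,
                 composite_dates = composite_dates),
            class = "migcues_landscape")
}

# Moving-average box blur with edge padding by truncation.
box_smooth <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  cs <- matrix(0, nr + 1, nc + 1)
  cs[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  for (i in seq_len(nr)) {
    r0 <- max(1, i - half); r1 <- min(nr, i + half)
    for (j in seq_len(nc)) {
      c0 <- max(1, j - half); c1 <- min(nc, j + half)
      s <- cs[r1 + 1, c1 + 1] - cs[r0, c1 + 1] - cs[r1 + 1, c0] + cs[r0, c0]
      out[i, j] <- s / ((r1 - r0 + 1) * (c1 - c0 + 1))
    }
  }
  out
}

#' @export
print.migcues_landscape <- function(x, ...) {
  cfg <- x$config
  cat("<migcues_landscape> ", cfg$grid_shape[1], "x", cfg$grid_shape[2],
      " cells of ", cfg$cell_size_m, " m; ",
      sum(x$refugia_mask), " refugia cells; season ",
      format(cfg$season_start), " to ", format(cfg$season_end), "\n", sep = "")
  invisible(x)
}

#' Canonical position of points in a periodic landscape
#'
#' Translates points into the grid extent modulo the landscape width/height
#' (no-op for points already inside, or when the landscape has `wrap =
#' FALSE`). All samplers canonicalize their inputs, so a bird hundreds of km
#' from the grid samples the periodic continuation of the same world.
#'
#' @param landscape A `migcues_landscape`.
#' @param lon,lat Coordinates (vectorised).
#' @return List with canonical `lon`, `lat`.
#' @export
canonicalize_lonlat <- function(landscape, lon, lat) {
  cfg <- landscape$config
  if (!isTRUE(cfg$wrap)) return(list(lon = lon, lat = lat))
  nr <- length(landscape$cell_lat); nc <- length(landscape$cell_lon)
  lat_ext <- nr * cfg$cell_size_m / landscape$m_per_deg_lat
  lon_ext <- nc * cfg$cell_size_m / landscape$m_per_deg_lon
  list(lon = cfg$origin_lon + (lon - cfg$origin_lon) %% lon_ext,
       lat = cfg$origin_lat + (lat - cfg$origin_lat) %% lat_ext)
}

# Row/col index of the cell containing each point (nearest centre).
cell_index <- function(landscape, lon, lat) {
  p <- canonicalize_lonlat(landscape, lon, lat)
  lon <- p$lon; lat <- p$lat
  nr <- length(landscape$cell_lat); nc <- length(landscape$cell_lon)
  dlat <- landscape$cell_lat[2] - landscape$cell_lat[1]
  dlon <- landscape$cell_lon[2] - landscape$cell_lon[1]
  row <- round((lat - landscape$cell_lat[1]) / dlat) + 1
  col <- round((lon - landscape$cell_lon[1]) / dlon) + 1
  bad <- row < 1 | row > nr | col < 1 | col > nc | is.na(row) | is.na(col)
  if (any(bad)) stop("point outside landscape extent at index ",
                     paste(head(which(bad), 5), collapse = ", "))
  list(row = as.integer(row), col = as.integer(col))
}

#' Deterministic base temperature of the landscape
#'
#' The diel/seasonal component shared by every cell: a cosine diel cycle
#' (minimum at 02:00, maximum at 14:00) plus a linear seasonal warming trend.
#' Cell temperature = base + that cell's static anomaly.
#'
#' @param landscape A `migcues_landscape`.
#' @param date Date (vectorised).
#' @param hour Hour of day 0-23 (vectorised).
#' @return Temperature in degrees C.
#' @export
base_temperature <- function(landscape, date, hour) {
  cfg <- landscape$config
  tmin <- cfg$base_diel_cycle[1]; tmax <- cfg$base_diel_cycle[2]
  # annually periodic: the seasonal trend restarts at each year's season-start
  # anniversary, so multi-year tracks see the same season every year
  date <- as.Date(date)
  anchor <- as.Date(sprintf("%s-%s", format(date, "%Y"),
                            format(cfg$season_start, "%m-%d")))
  d <- as.numeric(date - anchor)
  tmin + (tmax - tmin) * 0.5 * (1 + cos(2 * pi * (hour - 14) / 24)) +
    cfg$seasonal_trend_C_per_day * d
}

# TRUE when a date's month-day falls inside the landscape's seasonal window
# (the temperature series repeats every year).
date_covered <- function(config, date) {
  md <- format(as.Date(date), "%m-%d")
  md >= format(config$season_start, "%m-%d") &
    md <= format(config$season_end, "%m-%d")
}

#' Cell temperature at points and times
#'
#' @param landscape A `migcues_landscape`.
#' @param lon,lat Point coordinates (vectorised).
#' @param time POSIXct (UTC); matched to the nearest hour, ties to the earlier
#'   hour.
#' @return Temperature (degrees C) of the containing cell at that hour.
#' @export
temperature_at <- function(landscape, lon, lat, time) {
  idx <- cell_index(landscape, lon, lat)
  hr <- nearest_hour(time)
  base_temperature(landscape, hr$date, hr$hour) +
    landscape$anomaly[cbind(idx$row, idx$col)]
}

# Nearest hour with ties broken toward the earlier hour; rolls across days.
nearest_hour <- function(time) {
  secs <- as.numeric(as.POSIXct(time, tz = "UTC"))
  h <- floor(secs / 3600)
  frac <- secs / 3600 - h
  h <- h + (frac > 0.5)
  list(date = as.Date(as.POSIXct(h * 3600, origin = "1970-01-01", tz = "UTC")),
       hour = as.integer(h %% 24))
}

# Seasonal NDVI multiplier: plateau at 1 until the peak day, then linear
# senescence, floored at 0.
ndvi_season_factor <- function(config, date) {
  d <- doy(date)
  pmax(0, 1 - config$ndvi_senescence_rate * pmax(0, d - config$ndvi_peak_day))
}

#' NDVI at points, matched to the nearest 8-day composite
#'
#' Returns the value of the composite whose nominal date is nearest the fix
#' date (ties to the earlier composite), for the cell containing each point.
#'
#' @param landscape A `migcues_landscape`.
#' @param lon,lat Point coordinates (vectorised).
#' @param date Date of each point.
#' @return NDVI in `[0, 1]`.
#' @export
ndvi_at <- function(landscape, lon, lat, date) {
  idx <- cell_index(landscape, lon, lat)
  comp <- nearest_composite(landscape$composite_dates, as.Date(date))
  landscape$greenness[cbind(idx$row, idx$col)] *
    ndvi_season_factor(landscape$config, comp)
}

# Nearest composite date; exact midpoints resolve to the earlier composite.
# Matching is on day-of-year, so the 8-day calendar repeats every year.
nearest_composite <- function(composite_dates, date) {
  stopifnot(length(composite_dates) >= 1)
  comp_doy <- doy(composite_dates)
  i <- vapply(doy(as.Date(date)), function(d) {
    dd <- abs(comp_doy - d)
    which(dd == min(dd))[1]  # earlier wins on ties (dates are sorted)
  }, integer(1))
  composite_dates[i]
}

#' Fraction of refugia cells within a radius of a point
#'
#' Truth-side covariate for simulated birds: the share of grid cells whose
#' centre lies within `radius_m` (geodesic) of the point that belong to a cool
#' microrefugium patch.
#'
#' @param landscape A `migcues_landscape`.
#' @param lon,lat Point coordinates (vectorised).
#' @param radius_m Buffer radius in metres (default 500).
#' @return Fraction in `[0, 1]`.
#' @export
refugia_fraction <- function(landscape, lon, lat, radius_m = 500) {
  mapply(function(x, y) {
    cells <- buffer_cells(landscape, x, y, radius_m)
    if (nrow(cells) == 0) return(NA_real_)
    mean(landscape$refugia_mask[cbind(cells$row, cells$col)])
  }, lon, lat)
}

# All cells whose centres lie within radius_m (geodesic) of a point.
# Searches only a candidate window around the containing cell.
buffer_cells <- function(landscape, lon, lat, radius_m) {
  p <- canonicalize_lonlat(landscape, lon, lat)
  lon <- p$lon; lat <- p$lat
  idx <- cell_index(landscape, lon, lat)
  w <- ceiling(radius_m / landscape$config$cell_size_m) + 1L
  rows <- max(1L, idx$row - w):min(length(landscape$cell_lat), idx$row + w)
  cols <- max(1L, idx$col - w):min(length(landscape$cell_lon), idx$col + w)
  grid <- expand.grid(row = rows, col = cols)
  d <- geosphere::distGeo(c(lon, lat),
                          cbind(landscape$cell_lon[grid$col],
                                landscape$cell_lat[grid$row]))
  complete <- idx$row - w >= 1 && idx$row + w <= length(landscape$cell_lat) &&
    idx$col - w >= 1 && idx$col + w <= length(landscape$cell_lon)
  out <- grid[d <= radius_m, , drop = FALSE]
  attr(out, "complete") <- complete
  out
}

#' Write / read a landscape as plain text
#'
#' Serialises a landscape to a directory: the config as YAML and each grid
#' (anomaly, refugia mask, greenness) as a headerless CSV matrix. Round-trips
#' exactly.
#'
#' @param landscape A `migcues_landscape`.
#' @param dir Directory path (created if needed).
#' @return `write_landscape()` returns `dir` invisibly; `read_landscape()`
#'   returns the landscape.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(landscape$config)
  cfg$season_start <- format(cfg$season_start)
  cfg$season_end <- format(cfg$season_end)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  utils::write.table(landscape$anomaly, file.path(dir, "anomaly.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(landscape$refugia_mask * 1L, file.path(dir, "refugia.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(landscape$greenness, file.path(dir, "greenness.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- landscape_config(
    grid_shape = cfg$grid_shape, cell_size_m = cfg$cell_size_m,
    origin_lon = cfg$origin_lon, origin_lat = cfg$origin_lat,
    n_refugia_patches = cfg$n_refugia_patches,
    refugia_cooling_C = cfg$refugia_cooling_C,
    base_diel_cycle = unlist(cfg$base_diel_cycle),
    seasonal_trend_C_per_day = cfg$seasonal_trend_C_per_day,
    noise_sd_C = cfg$noise_sd_C, ndvi_peak_day = cfg$ndvi_peak_day,
    ndvi_senescence_rate = cfg$ndvi_senescence_rate, year = cfg$year,
    season_start = cfg$season_start, season_end = cfg$season_end,
    wrap = cfg$wrap, seed = cfg$seed)
  land <- simulate_landscape(config)
  # grids are regenerated from the seed; read back to guarantee equality with
  # what was written even if the file was produced elsewhere
  rd <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = ","))
  land$anomaly <- unname(rd("anomaly.csv"))
  land$refugia_mask <- unname(rd("refugia.csv")) == 1
  land$greenness <- unname(rd("greenness.csv"))
  land
}
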