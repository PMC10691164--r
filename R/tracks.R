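# Synthetic GPS tracks of partially migratory birds. Each migrant's true
# departure day is a linear function of its (deterministically recomputable)
# breeding-site covariates -- greenness, temperature anomaly and microrefugia
# availability -- plus an individual intercept shared across years and a
# per-year residual, so downstream recovery of effect sizes and repeatability
# can be checked against ground truth.

#' Simulate GPS tracks with known migratory ground truth
#'
#' Places birds on a synthetic landscape, draws migration strategy and sites,
#' builds true departure/return dates from configurable covariate effects, and
#' emits a fix table (one GPS position per interval) plus a truth table.
#' Migration is a one-day relocation between a breeding and a post-breeding
#' site; birds otherwise scatter around the active site within a home range.
#'
#' @param landscape A `migcues_landscape` from [simulate_landscape()].
#' @param effect_sizes Named list of days-per-SD effects on true departure:
#'   `beta_ndvi_days`, `beta_refugia_days`, `beta_temp_days`,
#'   `interaction_refugia_temp`. Covariates are z-scored across birds.
#' @param n_birds Total birds (>= 2).
#' @param years Consecutive breeding seasons per bird (sites are reused;
#'   timing is redrawn each year around the same individual intercept).
#' @param n_residents Number of birds assigned the resident strategy.
#' @param fix_interval_min Minutes between fixes, in 10..120 (default 120,
#'   matching a 2 h duty cycle).
#' @param gps_noise_sd_m GPS position error SD in metres (default 25).
#' @param home_range_sd_m SD of within-day scatter around the active site.
#' @param departure_baseline_doy Baseline true departure day of year
#'   (default 171 = 20 June in a non-leap year).
#' @param departure_sd_days SD of the per-year residual on departure (default 3).
#' @param individual_sd_days SD of the individual random intercept shared
#'   across years (default 4).
#' @param return_baseline_days,return_sd_days,return_individual_sd_days True
#'   return date as days after 1 September: baseline (default 89 = 29 Nov),
#'   per-year SD and individual-intercept SD.
#' @param migrant_distance_range_km Bounds of migrant site separation
#'   (default 4 to 421 km); distances are drawn log-uniformly.
#' @param dropout_prob Probability that a migrant's tag dies between departure
#'   and return (uniform end date), censoring the return.
#' @param seed RNG seed.
#' @return A list with `fixes` (tibble: bird_id, timestamp, lon, lat) and
#'   `truth` (tibble: one row per bird-year with strategy, true dates, sites,
#'   `distance_km`, intercepts, and the raw + z-scored covariates
#'   `cov_ndvi`/`cov_temp`/`cov_refugia`).
#' @export
#' @examples
#' land <- simulate_landscape(landscape_config(seed = 2))
#' sim <- simulate_tracks(land, n_birds = 3, seed = 2)
#' head(sim$truth)
simulate_tracks <- function(landscape,
                            effect_sizes = list(beta_ndvi_days = 8,
                                                beta_refugia_days = 4,
                                                beta_temp_days = 0,
                                                interaction_refugia_temp = -3),
                            n_birds = 20L,
                            years = 1L,
                            n_residents = max(0L, round(0.1 * n_birds)),
                            fix_interval_min = 120L,
                            gps_noise_sd_m = 25,
                            home_range_sd_m = 150,
                            departure_baseline_doy = 171L,
                            departure_sd_days = 3,
                            individual_sd_days = 4,
                            return_baseline_days = 89L,
                            return_sd_days = 30,
                            return_individual_sd_days = 10,
                            migrant_distance_range_km = c(4, 421),
                            dropout_prob = 0,
                            seed = 1L) {
  stopifnot(inherits(landscape, "migcues_landscape"),
            n_birds >= 2, n_residents >= 0, n_residents < n_birds,
            fix_interval_min >= 10, fix_interval_min <= 120,
            years >= 1, migrant_distance_range_km[1] > 0)
  eff <- modifyList(list(beta_ndvi_days = 0, beta_refugia_days = 0,
                         beta_temp_days = 0, interaction_refugia_temp = 0),
                    as.list(effect_sizes))
  cfg <- landscape$config
  set.seed(child_seed(seed, 1L))

  # Breeding sites: cell centres far enough from the grid edge that the 500 m
  # buffer of every scattered fix stays complete.
  w <- ceiling((500 + 4 * sqrt(home_range_sd_m^2 + gps_noise_sd_m^2)) /
                 cfg$cell_size_m) + 2L
  nr <- length(landscape$cell_lat); nc <- length(landscape$cell_lon)
  if (nr <= 2 * w || nc <= 2 * w) {
    stop("landscape too small to place birds with a full 500 m buffer: needs ",
         "more than ", 2 * w, " cells per side")
  }
  rows <- sample((w + 1):(nr - w), n_birds, replace = TRUE)
  cols <- sample((w + 1):(nc - w), n_birds, replace = TRUE)
  br_lon <- landscape$cell_lon[cols]
  br_lat <- landscape$cell_lat[rows]

  # Deterministic covariates of the breeding site.
  cov_ndvi <- landscape$greenness[cbind(rows, cols)]
  cov_temp <- landscape$anomaly[cbind(rows, cols)]
  cov_refugia <- refugia_fraction(landscape, br_lon, br_lat, 500)
  zsc <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, length(x))
  z_ndvi <- zsc(cov_ndvi); z_temp <- zsc(cov_temp); z_ref <- zsc(cov_refugia)

  strategy <- rep("migrant", n_birds)
  if (n_residents > 0) strategy[sample(n_birds, n_residents)] <- "resident"

  # Post-breeding sites: drawn log-uniformly in distance, rejecting sites
  # whose canonical position in the periodic landscape falls too close to the
  # grid edge (keeps post-breeding buffers complete).
  pb_lon <- br_lon; pb_lat <- br_lat
  dist_km <- rep(0, n_birds)
  for (i in which(strategy == "migrant")) {
    for (try in 1:200) {
      d <- exp(runif(1, log(migrant_distance_range_km[1]),
                     log(migrant_distance_range_km[2])))
      p <- geosphere::destPoint(c(br_lon[i], br_lat[i]), runif(1, 0, 360),
                                d * 1000)
      can <- canonicalize_lonlat(landscape, p[1], p[2])
      idx <- cell_index(landscape, can$lon, can$lat)
      if (idx$row > w && idx$row <= nr - w && idx$col > w && idx$col <= nc - w) {
        pb_lon[i] <- p[1]; pb_lat[i] <- p[2]
        break
      }
    }
    if (pb_lon[i] == br_lon[i] && pb_lat[i] == br_lat[i]) {
      stop("could not place a post-breeding site for bird ", i,
           " with a complete buffer; use a larger landscape")
    }
    dist_km[i] <- geo_dist_km(br_lon[i], br_lat[i], pb_lon[i], pb_lat[i])
  }

  b_ind <- rnorm(n_birds, 0, individual_sd_days)
  b_ret <- rnorm(n_birds, 0, return_individual_sd_days)
  linpred <- departure_baseline_doy +
    eff$beta_ndvi_days * z_ndvi + eff$beta_refugia_days * z_ref +
    eff$beta_temp_days * z_temp + eff$interaction_refugia_temp * z_ref * z_temp

  truth <- vector("list", n_birds * years)
  fixes <- vector("list", n_birds * years)
  k <- 0L
  for (i in seq_len(n_birds)) {
    for (y in seq_len(years)) {
      k <- k + 1L
      yr <- cfg$year + (y - 1L)
      season_start <- as.Date(sprintf("%d-04-01", yr))
      # consecutive seasons abut at 31 March; the final season runs through
      # 30 April so the last return is observable
      season_close <- if (y < years) as.Date(sprintf("%d-03-31", yr + 1L)) else
        as.Date(sprintf("%d-04-30", yr + 1L))
      sep1 <- as.Date(sprintf("%d-09-01", yr))

      if (strategy[i] == "migrant") {
        dep_doy <- round(linpred[i] + b_ind[i] + rnorm(1, 0, departure_sd_days))
        if (dep_doy < 100 || dep_doy > 244) {
          stop("true departure day ", dep_doy, " for bird ", i,
               " falls outside the simulated season (day 100-244); ",
               "reduce the effect sizes or noise")
        }
        dep <- as.Date(dep_doy - 1, origin = sprintf("%d-01-01", yr))
        ret_days <- round(return_baseline_days + b_ret[i] +
                            rnorm(1, 0, return_sd_days))
        ret <- sep1 + max(10, min(198, ret_days))  # late Sep to mid March
        track_end <- season_close
        censored <- FALSE
        if (dropout_prob > 0 && runif(1) < dropout_prob) {
          gap <- as.integer(ret - dep)
          if (gap > 35) {
            track_end <- dep + sample(31:(gap - 1), 1)
            censored <- TRUE
          }
        }
      } else {
        dep <- as.Date(NA); ret <- as.Date(NA)
        track_end <- season_close; censored <- FALSE
      }

      truth[[k]] <- tibble::tibble(
        bird_id = sprintf("bird_%02d", i), season_year = yr,
        strategy = strategy[i],
        true_departure_date = dep, true_return_date = ret,
        track_end = track_end, return_censored = censored,
        breeding_lon = br_lon[i], breeding_lat = br_lat[i],
        postbreeding_lon = pb_lon[i], postbreeding_lat = pb_lat[i],
        distance_km = dist_km[i],
        individual_intercept_days = b_ind[i],
        cov_ndvi = cov_ndvi[i], cov_temp = cov_temp[i],
        cov_refugia = cov_refugia[i],
        z_ndvi = z_ndvi[i], z_temp = z_temp[i], z_refugia = z_ref[i])

      fixes[[k]] <- segment_fixes(
        bird_id = sprintf("bird_%02d", i),
        start = season_start, end = min(track_end, season_close),
        departure = dep, return_date = ret,
        breeding = c(br_lon[i], br_lat[i]),
        postbreeding = c(pb_lon[i], pb_lat[i]),
        fix_interval_min = fix_interval_min,
        scatter_sd_m = sqrt(home_range_sd_m^2 + gps_noise_sd_m^2))
    }
  }
  list(fixes = dplyr::arrange(dplyr::bind_rows(fixes), .data$bird_id,
                              .data$timestamp),
       truth = dplyr::bind_rows(truth))
}

# Fixes for one bird-season: at the breeding site before departure and after
# return, at the post-breeding site in between; iid metric scatter around the
# active site (home-range wander + GPS error combined).
segment_fixes <- function(bird_id, start, end, departure, return_date,
                          breeding, postbreeding, fix_interval_min,
                          scatter_sd_m) {
  days <- seq(start, end, by = 1)
  away <- if (is.na(departure)) rep(FALSE, length(days)) else {
    days >= departure & (is.na(return_date) | days < return_date)
  }
  mins <- seq(0, 24 * 60 - 1, by = fix_interval_min)
  n_per_day <- length(mins)
  n <- length(days) * n_per_day
  ts <- as.POSIXct(rep(days, each = n_per_day), tz = "UTC") +
    rep(mins, times = length(days)) * 60
  site_lon <- ifelse(rep(away, each = n_per_day), postbreeding[1], breeding[1])
  site_lat <- ifelse(rep(away, each = n_per_day), postbreeding[2], breeding[2])
  if (scatter_sd_m > 0) {
    p <- offset_lonlat(site_lon, site_lat,
                       rnorm(n, 0, scatter_sd_m), rnorm(n, 0, scatter_sd_m))
    site_lon <- p$lon; site_lat <- p$lat
  }
  tibble::tibble(bird_id = bird_id, timestamp = ts,
                 lon = site_lon, lat = site_lat)
}

#' Simulate a balanced trait panel with known repeatability
#'
#' Draws `trait = mu + b_i + e_iy` for `n_ind` individuals over `n_years`
#' years, with variance components chosen so the true intra-class correlation
#' is `icc`. Used to check repeatability estimation against ground truth.
#'
#' @param n_ind Number of individuals.
#' @param n_years Observations (years) per individual.
#' @param icc True intra-class correlation in `[0, 1)`.
#' @param total_var Total variance (individual + residual), default 100.
#' @param mu Grand mean, default 171 (a departure day of year).
#' @param n_populations Breeding populations assigned round-robin (a small
#'   population random effect of SD 1 is added on top, mirroring a
#'   multi-population study design).
#' @param seed RNG seed.
#' @return Tibble: bird_id, population_id, year, trait.
#' @export
simulate_trait_panel <- function(n_ind = 40L, n_years = 3L, icc = 0.64,
                                 total_var = 100, mu = 171,
                                 n_populations = 5L, seed = 1L) {
  stopifnot(icc >= 0, icc < 1, total_var > 0)
  set.seed(child_seed(seed, 2L))
  sd_ind <- sqrt(icc * total_var)
  sd_res <- sqrt((1 - icc) * total_var)
  b <- rnorm(n_ind, 0, sd_ind)
  pop <- rep_len(seq_len(n_populations), n_ind)
  u <- rnorm(n_populations, 0, 1)
  tidyr::expand_grid(i = seq_len(n_ind), year = seq_len(n_years)) |>
    dplyr::mutate(bird_id = sprintf("bird_%03d", .data$i),
                  population_id = sprintf("pop_%d", pop[.data$i]),
                  trait = mu + u[pop[.data$i]] + b[.data$i] +
                    rnorm(dplyr::n(), 0, sd_res)) |>
    dplyr::select("bird_id", "population_id", "year", "trait")
}

#' Simulate a cue-model frame with known covariate effects
#'
#' One row per migratory bird-season with standardized environmental
#' covariates (refugia availability, relative temperature exposure, relative
#' NDVI) and a departure day generated from a linear predictor with an
#' individual random intercept, for parameter-recovery checks of the
#' departure-date mixed model and AICc selection.
#'
#' @param n_birds Number of birds; each contributes `years` rows.
#' @param years Seasons per bird.
#' @param beta Named vector of true effects in days per SD on
#'   `refugia_pct`, `rel_temp`, `rel_ndvi`, and `refugia_x_temp` (interaction).
#' @param baseline_doy Intercept (default 171).
#' @param individual_sd Random-intercept SD (default 2).
#' @param resid_sd Residual SD in days (default 3).
#' @param binary_beta Named vector of true log-odds effects (same covariate
#'   names, post-breeding variants `*_post`) for the late-return binary
#'   response; default all zero (the no-effect condition).
#' @param seed RNG seed.
#' @return Tibble: bird_id, population_id, season_year, covariates (breeding
#'   and post-breeding), `departure_doy`, `return_binary`, and breeding-site
#'   coordinates for correlogram diagnostics.
#' @export
simulate_model_frame <- function(n_birds = 30L, years = 2L,
                                 beta = c(refugia_pct = 0, rel_temp = 0,
                                          rel_ndvi = 8, refugia_x_temp = 0),
                                 baseline_doy = 171,
                                 individual_sd = 2,
                                 resid_sd = 3,
                                 binary_beta = NULL,
                                 seed = 1L) {
  set.seed(child_seed(seed, 3L))
  bt <- c(refugia_pct = 0, rel_temp = 0, rel_ndvi = 0, refugia_x_temp = 0)
  bt[names(beta)] <- beta
  bb <- c(refugia_pct = 0, rel_temp = 0, rel_ndvi = 0,
          refugia_pct_post = 0, rel_temp_post = 0, rel_ndvi_post = 0)
  if (!is.null(binary_beta)) bb[names(binary_beta)] <- binary_beta
  b_ind <- rnorm(n_birds, 0, individual_sd)
  lon <- runif(n_birds, -8.5, -6.0); lat <- runif(n_birds, 37.8, 39.3)
  frame <- tidyr::expand_grid(i = seq_len(n_birds), yr = seq_len(years)) |>
    dplyr::mutate(
      bird_id = sprintf("bird_%03d", .data$i),
      population_id = sprintf("pop_%d", rep_len(1:3, n_birds)[.data$i]),
      season_year = 2014L + .data$yr,
      refugia_pct = rnorm(dplyr::n()),
      rel_temp = rnorm(dplyr::n()),
      rel_ndvi = rnorm(dplyr::n()),
      refugia_pct_post = rnorm(dplyr::n()),
      rel_temp_post = rnorm(dplyr::n()),
      rel_ndvi_post = rnorm(dplyr::n()),
      departure_doy = baseline_doy +
        bt["refugia_pct"] * .data$refugia_pct +
        bt["rel_temp"] * .data$rel_temp +
        bt["rel_ndvi"] * .data$rel_ndvi +
        bt["refugia_x_temp"] * .data$refugia_pct * .data$rel_temp +
        b_ind[.data$i] + rnorm(dplyr::n(), 0, resid_sd),
      breeding_lon = lon[.data$i], breeding_lat = lat[.data$i])
  eta <- with(frame, bb["refugia_pct"] * refugia_pct +
                bb["rel_temp"] * rel_temp + bb["rel_ndvi"] * rel_ndvi +
                bb["refugia_pct_post"] * refugia_pct_post +
                bb["rel_temp_post"] * rel_temp_post +
                bb["rel_ndvi_post"] * rel_ndvi_post)
  frame$return_binary <- as.integer(runif(nrow(frame)) < stats::plogis(eta))
  dplyr::select(frame, -"i", -"yr")
}
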