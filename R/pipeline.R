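# End-to-end driver: configuration, model-frame assembly, and the pipeline
# chaining phenology -> environmental sampling -> exposure indices ->
# repeatability -> cue models, with a provenance manifest and optional CSV
# outputs for stage-level resume.

#' Pipeline configuration
#'
#' All thresholds of the analysis with their study defaults: 500 m buffer,
#' 0.5 degree C refugium threshold, 1.5 km in/out radius, one-month departure
#' rule, 7-day return confirmation and pre-departure minimum, breeding window
#' from 1 May, post-breeding window to 15 September, late-return cutoff
#' 30 November, 1000 repeatability and 500 correlogram bootstrap iterations.
#'
#' @param ... Named overrides of the defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    buffer_m = 500,
    refugia_threshold_C = 0.5,
    radius_km = 1.5,
    min_away_days = 30L,
    min_back_days = 7L,
    max_gap_days = 3L,
    min_predeparture_days = 7L,
    capture_deadline = "05-01",
    breeding_start = "05-01",
    postbreeding_end = "09-15",
    return_cutoff = "11-30",
    n_boot_repeatability = 1000L,
    n_boot_correlogram = 500L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  structure(modifyList(cfg, over), class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips exactly: writing then reading reproduces the config.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Assemble the cue-model frame
#'
#' One row per migratory bird-season joining the migration event with its
#' breeding-phase covariates (refugia percentage, relative temperature
#' exposure, relative NDVI), their post-breeding counterparts, the departure
#' day of year, and the late-return binary (1 when the return falls after the
#' cutoff, NA when censored).
#'
#' @param events [migration_events()] table.
#' @param summaries [season_env_summaries()] table.
#' @param indices [exposure_indices()] table.
#' @param return_cutoff Month-day string (default "11-30").
#' @param population_id Optional vector or single value labelling breeding
#'   populations (default "pop_1").
#' @return Tibble with columns `bird_id`, `population_id`, `season_year`,
#'   `departure_doy`, `return_binary`, `refugia_pct`, `rel_temp`, `rel_ndvi`,
#'   `refugia_pct_post`, `rel_temp_post`, `rel_ndvi_post`, `breeding_lon`,
#'   `breeding_lat`.
#' @export
build_model_frame <- function(events, summaries, indices,
                              return_cutoff = "11-30",
                              population_id = "pop_1") {
  mig <- events[events$strategy == "migrant", , drop = FALSE]
  refu <- summaries |>
    dplyr::select("bird_id", "season_year", "phase", "refugia_pct") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "refugia_pct") |>
    dplyr::rename(refugia_pct = "breeding", refugia_pct_post = "postbreeding")
  expo <- indices |>
    dplyr::mutate(var = paste0(
      ifelse(.data$response == "temperature", "rel_temp", "rel_ndvi"),
      ifelse(.data$phase == "postbreeding", "_post", ""))) |>
    dplyr::select("bird_id", "season_year", "var", "index") |>
    tidyr::pivot_wider(names_from = "var", values_from = "index")
  cutoff <- as.Date(sprintf("%d-%s", mig$season_year, return_cutoff))
  mig |>
    dplyr::mutate(population_id = population_id,
                  departure_doy = doy(.data$departure_date),
                  return_binary = dplyr::if_else(
                    is.na(.data$return_date), NA_integer_,
                    as.integer(.data$return_date > cutoff))) |>
    dplyr::left_join(refu, by = c("bird_id", "season_year")) |>
    dplyr::left_join(expo, by = c("bird_id", "season_year")) |>
    dplyr::select("bird_id", "population_id", "season_year", "departure_doy",
                  "return_binary", dplyr::any_of(c(
                    "refugia_pct", "rel_temp", "rel_ndvi", "refugia_pct_post",
                    "rel_temp_post", "rel_ndvi_post")),
                  "breeding_lon", "breeding_lat")
}

#' Run the full analysis pipeline
#'
#' Chains all stages on a fix table and landscape: migration events
#' (phenology), environmental sampling, daily averaging, seasonal refugia
#' summaries, exposure indices, the cue-model frame, collinearity screening,
#' repeatability of the three migratory traits, AICc selection for departure
#' and return models, and a spline correlogram of the top departure model's
#' residuals. Stages whose sample-size preconditions are not met (e.g.
#' repeatability with single-year tracking) are recorded as skipped in the
#' manifest rather than failing the run. Deterministic given the config seed.
#'
#' @param fixes Fix table (`bird_id`, `timestamp`, `lon`, `lat`).
#' @param landscape A `migcues_landscape` covering the fix locations.
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, every stage output is also
#'   written as CSV (plus `manifest.yaml`).
#' @return A `migcues_run` list: `events`, `exclusions`, `env_samples`,
#'   `daily`, `summaries`, `indices`, `frame`, `collinearity`,
#'   `repeatability`, `departure_selection`, `return_selection`,
#'   `correlogram`, `manifest`.
#' @export
run_pipeline <- function(fixes, landscape, config = run_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  notes <- character()

  events <- migration_events(
    fixes, radius_km = config$radius_km,
    min_away_days = config$min_away_days,
    min_back_days = config$min_back_days,
    max_gap_days = config$max_gap_days,
    min_predeparture_days = config$min_predeparture_days,
    capture_deadline = config$capture_deadline)
  exclusions <- phenology_exclusions(events)

  env <- suppressMessages(sample_environment(
    fixes, landscape, buffer_m = config$buffer_m,
    refugia_threshold_C = config$refugia_threshold_C, skip_uncovered = TRUE))
  daily <- daily_env(env)
  summaries <- suppressMessages(season_env_summaries(
    env, events, breeding_start = config$breeding_start,
    postbreeding_end = config$postbreeding_end,
    refugia_threshold_C = config$refugia_threshold_C))
  indices <- suppressMessages(exposure_indices(
    daily, events, breeding_start = config$breeding_start,
    postbreeding_end = config$postbreeding_end))
  frame <- build_model_frame(events, summaries, indices,
                             return_cutoff = config$return_cutoff)

  covs <- intersect(c("refugia_pct", "rel_temp", "rel_ndvi"), names(frame))
  screen <- tryCatch(screen_collinearity(frame, covs),
                     error = function(e) { notes <<- c(notes,
                       paste("collinearity skipped:", conditionMessage(e)));
                       NULL })

  rpt <- tryCatch(
    repeatability_set(events, n_boot = config$n_boot_repeatability,
                      seed = config$seed),
    error = function(e) { notes <<- c(notes,
      paste("repeatability skipped:", conditionMessage(e))); NULL })

  dep_sel <- tryCatch(
    suppressWarnings(select_models(frame, "departure")),
    error = function(e) { notes <<- c(notes,
      paste("departure selection skipped:", conditionMessage(e))); NULL })

  ret_frame <- frame[!is.na(frame$return_binary), , drop = FALSE]
  ret_sel <- tryCatch(
    suppressWarnings(select_models(ret_frame, "return", max_terms = 3L)),
    error = function(e) { notes <<- c(notes,
      paste("return selection skipped:", conditionMessage(e))); NULL })

  correlogram <- NULL
  if (!is.null(dep_sel)) {
    top <- attr(dep_sel, "top_fit")
    used <- frame[complete.cases(frame[covs]), , drop = FALSE]
    correlogram <- tryCatch(
      spline_correlogram(resid(top), used$breeding_lon, used$breeding_lat,
                         n_boot = config$n_boot_correlogram,
                         seed = config$seed),
      error = function(e) { notes <<- c(notes,
        paste("correlogram skipped:", conditionMessage(e))); NULL })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("migcues")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    n_fixes = nrow(fixes),
    n_birds = length(unique(fixes$bird_id)),
    n_bird_seasons = nrow(events),
    n_migrant_seasons = sum(events$strategy == "migrant"),
    n_resident_seasons = sum(events$strategy == "resident"),
    n_excluded = nrow(exclusions),
    exclusion_reasons = as.list(table(exclusions$reason)),
    notes = if (length(notes)) notes else list())

  run <- structure(list(events = events, exclusions = exclusions,
                        env_samples = env, daily = daily,
                        summaries = summaries, indices = indices,
                        frame = frame, collinearity = screen,
                        repeatability = rpt,
                        departure_selection = dep_sel,
                        return_selection = ret_sel,
                        correlogram = correlogram,
                        manifest = manifest),
                   class = "migcues_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.migcues_run <- function(x, ...) {
  m <- x$manifest
  cat("<migcues_run> ", m$n_birds, " birds, ", m$n_bird_seasons,
      " bird-seasons (", m$n_migrant_seasons, " migrant / ",
      m$n_resident_seasons, " resident), ", m$n_excluded, " excluded\n",
      sep = "")
  if (!is.null(x$repeatability)) print(tibble::as_tibble(x$repeatability))
  invisible(x)
}

# Write every tabular stage output as CSV plus the manifest as YAML.
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df) && nrow(df)) {
      readr::write_csv(tibble::as_tibble(df), file.path(out_dir, name))
    }
  }
  wr(run$events, "events.csv")
  wr(run$exclusions, "exclusions.csv")
  wr(run$env_samples, "env_samples.csv")
  wr(run$daily, "daily_env.csv")
  wr(run$summaries, "season_summaries.csv")
  wr(run$indices, "exposure_indices.csv")
  wr(run$frame, "model_frame.csv")
  if (!is.null(run$repeatability)) wr(run$repeatability, "repeatability.csv")
  if (!is.null(run$departure_selection)) {
    wr(run$departure_selection, "selection_departure.csv")
  }
  if (!is.null(run$return_selection)) {
    wr(run$return_selection, "selection_return.csv")
  }
  if (!is.null(run$correlogram)) wr(run$correlogram, "correlogram.csv")
  yaml::write_yaml(run$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Departure-date distribution plot
#'
#' @param events [migration_events()] table.
#' @return A ggplot histogram of migrant departure dates with the median
#'   marked.
#' @export
plot_departure_dates <- function(events) {
  mig <- events[events$strategy == "migrant", , drop = FALSE]
  ggplot2::ggplot(mig, ggplot2::aes(x = .data$departure_date)) +
    ggplot2::geom_histogram(binwidth = 7, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = median(mig$departure_date),
                        linetype = "dashed") +
    ggplot2::labs(x = "Departure date", y = "Bird-seasons",
                  title = "Departure from the breeding area") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.population_smooth <- function(object, ...) {
  grid <- seq(object$doy_range[1], object$doy_range[2])
  df <- tibble::tibble(doy = grid, fitted = predict(object, grid))
  obs <- object$model$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$doy)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$y),
                        alpha = 0.2, size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "Day of year", y = object$response,
                  title = "Population seasonal smooth") +
    ggplot2::theme_minimal()
}
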