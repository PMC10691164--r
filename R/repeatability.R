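# Repeatability (intra-class correlation) of migratory traits across years,
# from Gaussian mixed-model variance components with a parametric-bootstrap
# percentile confidence interval.

# Trait vectors from a migration-event table. Dates become numeric axes:
# departure as day of year; return as days since 1 September of the season
# year, which keeps midwinter returns on a continuous axis across 31 Dec.
trait_values <- function(events, trait) {
  switch(trait,
    departure = ifelse(events$strategy == "migrant",
                       doy(events$departure_date), NA_real_),
    return = ifelse(events$strategy == "migrant" &
                      !is.na(events$return_date),
                    as.numeric(as.Date(events$return_date) -
                      as.Date(sprintf("%d-09-01", events$season_year))),
                    NA_real_),
    distance = events$distance_site_km,
    distance_cumulative = events$distance_cumulative_km,
    if (trait %in% names(events)) events[[trait]] else
      stop("unknown trait: ", trait))
}

#' Repeatability of a migratory trait
#'
#' Estimates the intra-class correlation R of a trait across repeated
#' bird-seasons: a Gaussian mixed model with a random intercept per individual
#' (and per breeding population, when a `population_id` column with more than
#' one level is present) is fitted by REML, and
#' R = sigma^2_individual / (sigma^2_individual + sigma^2_residual).
#' The population variance is partialled out as a random effect and excluded
#' from the denominator (adjusted repeatability); set
#' `population_in_denominator = TRUE` for the unadjusted alternative.
#' Uncertainty comes from a parametric bootstrap: `n_boot` response vectors
#' are simulated from the fitted model, each refitted, and the 2.5/97.5
#' percentiles of the simulated R values form the interval.
#'
#' @param events A [migration_events()] table (optionally with
#'   `population_id`), or any data frame with `bird_id` and a numeric trait
#'   column.
#' @param trait "departure" (day of year), "return" (days since 1 Sep),
#'   "distance" (`distance_site_km`), "distance_cumulative", or the name of a
#'   numeric column.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Seed driving all bootstrap simulation.
#' @param population_in_denominator Include the population variance component
#'   in the denominator (default FALSE).
#' @return A `repeatability` object: `trait`, `R`, `ci_low`, `ci_high`,
#'   `n_individuals`, `n_observations`, `n_boot`, `n_dropped`, `seed`,
#'   `boundary` (TRUE when the individual variance collapsed to zero), and the
#'   fitted model.
#' @export
#' @examples
#' panel <- simulate_trait_panel(n_ind = 15, n_years = 3, icc = 0.6, seed = 4)
#' estimate_repeatability(panel, "trait", n_boot = 50, seed = 4)
estimate_repeatability <- function(events, trait, n_boot = 1000L, seed = 1L,
                                   population_in_denominator = FALSE) {
  y <- trait_values(events, trait)
  df <- data.frame(y = y, bird_id = factor(events$bird_id))
  has_pop <- "population_id" %in% names(events) &&
    length(unique(events$population_id[!is.na(y)])) > 1
  if (has_pop) df$population_id <- factor(events$population_id)
  df <- df[!is.na(df$y), , drop = FALSE]
  n_rep <- sum(table(df$bird_id) >= 2)
  if (nrow(df) < 4 || n_rep < 2) {
    stop("need at least 2 individuals with repeated observations; have ", n_rep)
  }
  form <- if (has_pop) y ~ 1 + (1 | bird_id) + (1 | population_id) else
    y ~ 1 + (1 | bird_id)
  # boundary traits (e.g. distances identical across years) trip lme4's
  # convergence heuristics; the boundary flag below reports them
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))

  icc_of <- function(m) {
    vc <- as.data.frame(lme4::VarCorr(m))
    v_ind <- vc$vcov[vc$grp == "bird_id"]
    v_res <- vc$vcov[vc$grp == "Residual"]
    v_pop <- if (has_pop) vc$vcov[vc$grp == "population_id"] else 0
    denom <- v_ind + v_res + if (population_in_denominator) v_pop else 0
    if (denom <= 0) return(0)
    v_ind / denom
  }
  R <- icc_of(fit)
  boundary <- R < 1e-10

  boots <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(child_seed(seed, 1000L + b))
    ysim <- simulate(fit)[[1]]
    boots[b] <- tryCatch(
      icc_of(suppressMessages(suppressWarnings(lme4::refit(fit, ysim)))),
      error = function(e) NA_real_)
  }
  dropped <- sum(is.na(boots))
  if (dropped > 0.05 * n_boot) {
    stop(dropped, " of ", n_boot, " bootstrap replicates failed to converge")
  }
  ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  if (R < ci[1] || R > ci[2]) {
    warning("percentile interval excludes the point estimate (boundary fit); ",
            "reported as-is")
  }
  structure(list(trait = trait, R = R, ci_low = ci[1], ci_high = ci[2],
                 n_individuals = length(unique(df$bird_id)),
                 n_observations = nrow(df), n_boot = as.integer(n_boot),
                 n_dropped = dropped, seed = seed, boundary = boundary,
                 boot_values = boots, model = fit),
            class = "repeatability")
}

#' Is a repeatability estimate significant?
#'
#' Significant when the 95% bootstrap interval excludes zero (its lower bound
#' is above 0); an interval overlapping R = 0 is not.
#'
#' @param estimate A `repeatability` object (or anything with `ci_low`).
#' @return Logical.
#' @export
repeatability_significance <- function(estimate) {
  estimate$ci_low > 0
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("<repeatability> %s: R = %.3f [%.3f, %.3f] (n = %d birds, %d obs, %d boot)%s\n",
              x$trait, x$R, x$ci_low, x$ci_high, x$n_individuals,
              x$n_observations, x$n_boot,
              if (x$boundary) " [boundary: individual variance ~ 0]" else ""))
  invisible(x)
}

#' @export
tidy.repeatability <- function(x, ...) {
  tibble::tibble(trait = x$trait, R = x$R, ci_low = x$ci_low,
                 ci_high = x$ci_high,
                 significant = repeatability_significance(x))
}

#' @export
glance.repeatability <- function(x, ...) {
  tibble::tibble(trait = x$trait, R = x$R, ci_low = x$ci_low,
                 ci_high = x$ci_high, n_individuals = x$n_individuals,
                 n_observations = x$n_observations, n_boot = x$n_boot,
                 n_dropped = x$n_dropped, boundary = x$boundary,
                 seed = x$seed)
}

#' Repeatability of several traits at once
#'
#' @param events See [estimate_repeatability()].
#' @param traits Character vector of traits (default the three study traits).
#' @param ... Passed to [estimate_repeatability()].
#' @return A `repeatability_set` tibble (one tidy row per trait), ready for
#'   [autoplot()] as a forest plot.
#' @export
repeatability_set <- function(events,
                              traits = c("distance", "departure", "return"),
                              ...) {
  rows <- purrr::map(traits, function(tr) {
    est <- estimate_repeatability(events, tr, ...)
    dplyr::bind_cols(tidy(est),
                     tibble::tibble(n_individuals = est$n_individuals,
                                    n_observations = est$n_observations))
  })
  structure(dplyr::bind_rows(rows),
            class = c("repeatability_set", class(tibble::tibble())))
}

#' @export
autoplot.repeatability_set <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$trait, y = .data$R)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Repeatability (R)",
                  title = "Individual consistency of migratory traits") +
    ggplot2::theme_minimal()
}
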