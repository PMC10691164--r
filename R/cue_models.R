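# Mixed-effects cue models: collinearity screening, the departure-date LMM,
# the binomial early/late-return GLMM, AICc candidate-set selection, and
# spline correlogram diagnostics of residual spatial autocorrelation.

#' Collinearity screen
#'
#' Pairwise Pearson correlations and variance inflation factors for a set of
#' covariates. Violations (|r| >= 0.7 or VIF >= 3) are reported, never
#' auto-dropped; a perfectly collinear covariate gets an infinite VIF.
#'
#' @param frame Data frame of bird-seasons.
#' @param covariates Character vector of covariate columns (>= 2).
#' @return A `collinearity_screen` list: `r_matrix`, `vif` (named vector),
#'   `violations` (tibble of offending pairs/covariates).
#' @export
screen_collinearity <- function(frame, covariates) {
  stopifnot(length(covariates) >= 2, all(covariates %in% names(frame)))
  x <- as.data.frame(frame[covariates])
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) <= length(covariates) + 1) {
    stop("need more rows than covariates + 1 for the screen")
  }
  r <- stats::cor(x)
  vif <- vapply(covariates, function(v) {
    others <- setdiff(covariates, v)
    # perfect fits are legitimate input here (duplicated covariates)
    r2 <- suppressWarnings(
      summary(lm(stats::reformulate(others, v), data = x))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  pairs <- which(abs(r) >= 0.7 & upper.tri(r), arr.ind = TRUE)
  viol <- dplyr::bind_rows(
    tibble::tibble(type = rep("correlation", nrow(pairs)),
                   term = paste(rownames(r)[pairs[, 1]],
                                colnames(r)[pairs[, 2]], sep = " ~ "),
                   value = r[pairs]),
    tibble::tibble(type = "vif", term = names(vif), value = unname(vif)) |>
      dplyr::filter(.data$value >= 3))
  structure(list(r_matrix = r, vif = vif, violations = viol),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat("<collinearity_screen> ", length(x$vif), " covariates; ",
      nrow(x$violations), " violation(s)\n", sep = "")
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}

#' @export
tidy.collinearity_screen <- function(x, ...) {
  tibble::tibble(covariate = names(x$vif), vif = unname(x$vif),
                 max_abs_r = vapply(names(x$vif), function(v) {
                   max(abs(x$r_matrix[v, setdiff(colnames(x$r_matrix), v)]))
                 }, numeric(1)))
}

# Relaxed lmer controls: bird-season frames can have one season per bird.
lmm_control <- function() {
  lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    check.conv.singular = "ignore")
}
glmm_control <- function() {
  lme4::glmerControl(check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.nRE = "ignore",
                     check.conv.singular = "ignore")
}

#' Departure-date mixed model
#'
#' Gaussian linear mixed model of departure day of year on environmental
#' covariates with a random intercept per bird, fitted by REML via
#' [lmerTest::lmer()] so coefficient tests carry Satterthwaite degrees of
#' freedom.
#'
#' @param frame One row per migratory bird-season with `departure_doy`,
#'   `bird_id`, and the covariates.
#' @param terms Fixed-effect terms; interactions as `"a:b"`. Default is the
#'   full study structure: refugia availability, relative temperature
#'   exposure, their interaction, and relative NDVI.
#' @return A `departure_model` wrapping the fit.
#' @export
fit_departure_model <- function(frame,
                                terms = c("refugia_pct", "rel_temp",
                                          "rel_ndvi",
                                          "refugia_pct:rel_temp")) {
  stopifnot("departure_doy" %in% names(frame), "bird_id" %in% names(frame))
  if (length(unique(frame$bird_id)) < 5) {
    warning("fewer than 5 birds; random-intercept variance will be unstable")
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  f <- as.formula(paste("departure_doy ~", rhs, "+ (1 | bird_id)"))
  fit <- suppressMessages(lmerTest::lmer(f, data = frame, REML = TRUE,
                                         control = lmm_control()))
  structure(list(fit = fit, terms = terms), class = "departure_model")
}

#' @export
print.departure_model <- function(x, ...) {
  cat("<departure_model> departure_doy ~",
      paste(x$terms, collapse = " + "), "+ (1|bird_id)\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.departure_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, "Estimate"],
                 std_error = s[, "Std. Error"], df = s[, "df"],
                 statistic = s[, "t value"], p_value = s[, "Pr(>|t|)"])
}

#' @export
glance.departure_model <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble::tibble(n_obs = stats::nobs(x$fit),
                 n_birds = lme4::ngrps(x$fit)[["bird_id"]],
                 sigma_residual = sqrt(vc$vcov[vc$grp == "Residual"]),
                 sigma_bird = sqrt(vc$vcov[vc$grp == "bird_id"]),
                 logLik = as.numeric(logLik(x$fit)),
                 AICc = aicc(x$fit))
}

#' Marginal refugia slope at given temperature exposure
#'
#' The fitted effect of refugia availability on departure date as a function
#' of relative temperature exposure: main effect plus interaction times the
#' temperature value. Readouts at low vs high temperature show whether the
#' refugia benefit shrinks under hot conditions.
#'
#' @param model A `departure_model` containing `refugia_pct` and its
#'   interaction with `rel_temp`.
#' @param rel_temp Temperature exposure values at which to evaluate.
#' @return Tibble: `rel_temp`, `refugia_slope`.
#' @export
marginal_refugia_slope <- function(model, rel_temp) {
  b <- lme4::fixef(model$fit)
  if (!"refugia_pct" %in% names(b)) stop("model lacks a refugia_pct term")
  bi <- b[grep("^refugia_pct:rel_temp$|^rel_temp:refugia_pct$", names(b))]
  bi <- if (length(bi)) unname(bi) else 0
  tibble::tibble(rel_temp = rel_temp,
                 refugia_slope = unname(b["refugia_pct"]) + bi * rel_temp)
}

#' Early/late return mixed model
#'
#' Binomial logit mixed model of the probability of a late return (after
#' 30 November) on breeding- and post-breeding-season covariates, with a
#' random intercept per bird (Laplace approximation). On separation or
#' non-convergence the model is refitted with data-augmentation shrinkage
#' (every row mirrored with flipped response at small prior weight) and
#' flagged `penalized`.
#'
#' @param frame One row per bird-season with `return_binary` (1 = late) and
#'   covariates.
#' @param terms Fixed-effect terms (at most `max_terms`).
#' @param max_terms Cap on the number of fixed-effect terms (default 3).
#' @param penalty_weight Prior weight of each mirrored pseudo-observation in
#'   the fallback (default 0.05).
#' @return A `return_model`: fit, terms, `penalized` flag.
#' @export
fit_return_model <- function(frame, terms = character(), max_terms = 3L,
                             penalty_weight = 0.05) {
  stopifnot("return_binary" %in% names(frame))
  if (length(terms) > max_terms) {
    stop("at most ", max_terms, " fixed-effect terms per return model")
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  f <- as.formula(paste("return_binary ~", rhs, "+ (1 | bird_id)"))
  fit <- NULL
  bad <- FALSE
  withCallingHandlers(
    fit <- tryCatch(
      lme4::glmer(f, data = frame, family = stats::binomial("logit"),
                  control = glmm_control()),
      error = function(e) { bad <<- TRUE; NULL }),
    warning = function(w) {
      if (grepl("converge|Hessian|deviance|gradient|pwrss",
                conditionMessage(w))) {
        bad <<- TRUE
      }
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  if (!is.null(fit) && max(abs(lme4::fixef(fit))) > 15) bad <- TRUE
  penalized <- FALSE
  raw_fit <- fit
  if (bad || is.null(fit)) {
    aug <- frame
    aug$return_binary <- 1L - aug$return_binary
    dat <- dplyr::bind_rows(frame, aug)
    dat$.w <- c(rep(1, nrow(frame)), rep(penalty_weight, nrow(aug)))
    # nAGQ = 0 (PIRLS): the Laplace step is unreliable with the fractional
    # prior weights of the augmentation
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(f, data = dat, family = stats::binomial("logit"),
                  weights = dat$.w, nAGQ = 0L, control = glmm_control())))
    penalized <- TRUE
  }
  structure(list(fit = fit, raw_fit = raw_fit, terms = terms,
                 penalized = penalized),
            class = "return_model")
}

#' @export
print.return_model <- function(x, ...) {
  cat("<return_model> return_binary ~",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
      "+ (1|bird_id)", if (x$penalized) "[penalized]" else "", "\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.return_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, "Estimate"],
                 std_error = s[, "Std. Error"], statistic = s[, "z value"],
                 p_value = s[, "Pr(>|z|)"])
}

#' Small-sample corrected AIC
#'
#' AICc = AIC + 2k(k+1)/(n - k - 1), with k the number of estimated
#' parameters (from the log-likelihood degrees of freedom) and n the number of
#' observations.
#'
#' @param model A fitted model with [logLik()] and [stats::nobs()] methods.
#' @return AICc, or `NA` with a warning when `n - k - 1 <= 0`.
#' @export
aicc <- function(model) {
  ll <- logLik(model)
  k <- attr(ll, "df")
  n <- stats::nobs(model)
  if (n - k - 1 <= 0) {
    warning("AICc undefined: n - k - 1 <= 0 (n = ", n, ", k = ", k, ")")
    return(NA_real_)
  }
  AIC(model) + 2 * k * (k + 1) / (n - k - 1)
}

# Admissible term subsets: every subset of `terms` of size <= max_terms where
# each interaction "a:b" is accompanied by both main effects (marginality).
enumerate_term_sets <- function(terms, max_terms = Inf, marginality = TRUE) {
  sets <- list(character())
  for (m in seq_len(min(length(terms), max_terms))) {
    cmb <- utils::combn(terms, m, simplify = FALSE)
    sets <- c(sets, cmb)
  }
  if (!marginality) return(sets)
  Filter(function(s) {
    ints <- s[grepl(":", s)]
    all(vapply(ints, function(tt) {
      all(strsplit(tt, ":", fixed = TRUE)[[1]] %in% s)
    }, logical(1)))
  }, sets)
}

#' AICc model selection over a candidate term set
#'
#' Fits every admissible subset of the candidate terms (including the null
#' model) by maximum likelihood, ranks by AICc, and flags the plausible set
#' (delta AICc < 2 of the top model). For `response = "departure"` candidates
#' are Gaussian mixed models of `departure_doy`; for `"return"` binomial logit
#' mixed models of `return_binary`; both carry a bird random intercept.
#' Interactions require their main effects; AICc ties rank the model with
#' fewer parameters first. Candidates that fail to fit, or whose AICc is
#' undefined (n - k - 1 <= 0), are skipped with a warning.
#'
#' @param frame Model frame (one row per migratory bird-season).
#' @param response "departure" or "return".
#' @param candidate_terms Terms to enumerate over; defaults per response to
#'   the study's covariate sets.
#' @param max_terms Cap on terms per candidate (default Inf for departure;
#'   the study used 3 for return models).
#' @param marginality Enforce interaction marginality (default TRUE).
#' @return A `selection_table` tibble: `model`, `k`, `logLik`, `AICc`,
#'   `delta_AICc`, `weight`, `in_plausible_set`; the best model's fit is in
#'   attribute `top_fit`, all fits in attribute `fits`.
#' @export
select_models <- function(frame, response = c("departure", "return"),
                          candidate_terms = NULL, max_terms = Inf,
                          marginality = TRUE) {
  response <- match.arg(response)
  if (is.null(candidate_terms)) {
    candidate_terms <- if (response == "departure") {
      c("refugia_pct", "rel_temp", "rel_ndvi", "refugia_pct:rel_temp")
    } else {
      c("refugia_pct", "rel_temp", "rel_ndvi",
        "refugia_pct_post", "rel_temp_post", "rel_ndvi_post")
    }
  }
  if (response == "return" && is.infinite(max_terms)) max_terms <- 3L
  sets <- enumerate_term_sets(candidate_terms, max_terms, marginality)
  stopifnot(length(sets) <= 500)

  fit_one <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    if (response == "departure") {
      f <- as.formula(paste("departure_doy ~", rhs, "+ (1 | bird_id)"))
      suppressMessages(suppressWarnings(
        lme4::lmer(f, data = frame, REML = FALSE, control = lmm_control())))
    } else {
      rm <- fit_return_model(frame, terms, max_terms = max_terms)
      # likelihoods of penalized (augmented-data) fits are not comparable
      # with plain ones; use the unpenalized fit for AICc when it exists
      rm$raw_fit %||% rm$fit
    }
  }

  rows <- list(); fits <- list()
  for (s in sets) {
    label <- if (length(s)) paste(s, collapse = " + ") else "(null)"
    fit <- tryCatch(fit_one(s), error = function(e) NULL)
    if (is.null(fit)) {
      warning("candidate '", label, "' failed to fit; skipped")
      next
    }
    a <- withCallingHandlers(aicc(fit), warning = function(w) {
      warning("candidate '", label, "' skipped: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    if (is.na(a)) next
    ll <- logLik(fit)
    rows[[length(rows) + 1]] <- tibble::tibble(
      model = label, k = attr(ll, "df"), logLik = as.numeric(ll), AICc = a)
    fits[[label]] <- fit
  }
  tab <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$AICc, .data$k) |>
    dplyr::mutate(delta_AICc = .data$AICc - .data$AICc[1],
                  weight = exp(-0.5 * .data$delta_AICc) /
                    sum(exp(-0.5 * (.data$AICc - min(.data$AICc)))),
                  in_plausible_set = .data$delta_AICc < 2)
  tab <- structure(tab, class = c("selection_table", class(tab)))
  attr(tab, "top_fit") <- fits[[tab$model[1]]]
  attr(tab, "fits") <- fits
  attr(tab, "response") <- response
  tab
}

#' @export
autoplot.selection_table <- function(object, ...) {
  df <- dplyr::mutate(object,
                      model = factor(.data$model,
                                     levels = rev(.data$model)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_AICc, y = .data$model)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$in_plausible_set)) +
    ggplot2::geom_vline(xintercept = 2, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70"),
                               name = "dAICc < 2") +
    ggplot2::labs(x = "delta AICc", y = NULL,
                  title = "Candidate model ranking") +
    ggplot2::theme_minimal()
}

#' Spline correlogram of model residuals
#'
#' Nonparametric spatial autocorrelation: residuals are standardized, the
#' products of all location pairs are smoothed against pairwise geodesic
#' distance with a smoothing spline, and a 95% pointwise envelope is built by
#' resampling locations with replacement `n_boot` times.
#'
#' @param residuals Numeric residuals, one per location.
#' @param lon,lat Location coordinates (decimal degrees).
#' @param n_boot Bootstrap resamples (default 500).
#' @param seed RNG seed for the bootstrap.
#' @param n_grid Number of distance grid points (default 50).
#' @param df Spline degrees of freedom (default 6).
#' @return A `spline_correlogram` tibble: `distance_km`, `correlation`,
#'   `lower`, `upper`.
#' @export
spline_correlogram <- function(residuals, lon, lat, n_boot = 500L, seed = 1L,
                               n_grid = 50L, df = 6) {
  n <- length(residuals)
  stopifnot(length(lon) == n, length(lat) == n, n >= 10)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    dmat[i, j] <- dmat[j, i] <- geo_dist_km(lon[i], lat[i], lon[j], lat[j])
  }
  if (max(dmat) == 0) stop("all locations identical; correlogram undefined")
  z <- as.numeric(scale(residuals))

  corr_curve <- function(idx, grid) {
    pr <- which(upper.tri(dmat), arr.ind = TRUE)
    # pairs among the (possibly resampled) index vector, skipping pairs that
    # are the same original location twice
    ii <- idx[pr[, 1]]; jj <- idx[pr[, 2]]
    keep <- ii != jj
    d <- dmat[cbind(ii[keep], jj[keep])]
    s <- z[ii[keep]] * z[jj[keep]]
    if (length(unique(round(d, 6))) < 4) return(rep(NA_real_, length(grid)))
    fit <- stats::smooth.spline(d, s, df = min(df, length(unique(d)) - 1))
    predict(fit, grid)$y
  }

  grid <- seq(0, max(dmat), length.out = n_grid)
  est <- corr_curve(seq_len(n), grid)
  boots <- matrix(NA_real_, n_boot, n_grid)
  for (b in seq_len(n_boot)) {
    set.seed(child_seed(seed, 2000L + b))
    boots[b, ] <- corr_curve(sample(n, n, replace = TRUE), grid)
  }
  env <- apply(boots, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  structure(tibble::tibble(distance_km = grid, correlation = est,
                           lower = env[1, ], upper = env[2, ]),
            class = c("spline_correlogram", class(tibble::tibble())),
            n_locations = n, n_boot = n_boot, seed = seed)
}

#' @export
autoplot.spline_correlogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance_km)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$correlation)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Distance (km)", y = "Correlation",
                  title = "Spline correlogram of model residuals") +
    ggplot2::theme_minimal()
}
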