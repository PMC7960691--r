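#' Configuration for prevalence and coverage surface models
#'
#' @param df Spline basis dimension over age (penalised thin-plate spline).
#' @param covariates Character vector of covariate column names included on
#'   the logit scale (default the SDI-like development index).
#' @param covariate_sign Optional named vector of required coefficient signs
#'   (+1 or -1); a fitted coefficient violating its sign constraint is set
#'   to the boundary by refitting without that covariate.
#' @param random_effect Column used for random intercepts (`NULL` to drop).
#' @param n_draws Number of posterior draws per cell (default 1000, the
#'   draw count used for 95% uncertainty intervals).
#' @param seed Integer seed for the coefficient draws.
#' @return List of class `model_config`.
#' @export
model_config <- function(df = 8L, covariates = "sdi", covariate_sign = NULL,
                         random_effect = "location", n_draws = 1000L, seed = 1L) {
  stopifnot(n_draws >= 2L, df >= 1L)
  structure(list(df = as.integer(df), covariates = covariates,
                 covariate_sign = covariate_sign, random_effect = random_effect,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "model_config")
}

#' Fit a smooth prevalence surface for one severity band
#'
#' The meta-regression surrogate: a quasibinomial generalised additive
#' model on the logit scale (effective sample sizes as binomial weights,
#' Pearson dispersion absorbing non-sampling variance) with a penalised
#' spline over age, optional covariates, and location random intercepts,
#' fitted separately by sex. Posterior
#' draws are taken from the multivariate normal approximation to the
#' coefficient posterior (smoothing-parameter uncertainty included) and
#' mapped through the inverse logit on the prediction grid.
#'
#' @param data Harmonised prevalence rows for one dB band: columns
#'   `location`, `year`, `sex`, `age_low`, `prevalence`,
#'   `effective_sample_size`.
#' @param config A [model_config()].
#' @param covariates Covariate tibble (location, year, covariate columns),
#'   or `NULL` when the config lists none.
#' @param grid Prediction cells (location, year, sex, age_low). Default:
#'   all location-year-sex combinations observed in the data crossed with
#'   the observed age groups.
#' @return A [draw_surface()] keyed by the grid columns.
#' @export
fit_category_model <- function(data, config = model_config(), covariates = NULL,
                               grid = NULL) {
  if (is.null(grid)) {
    grid <- tidyr::crossing(
      dplyr::distinct(data[c("location", "year")]),
      sex = sort(unique(data$sex)),
      age_low = sort(unique(data$age_low))
    )
  }
  sexes <- sort(unique(grid$sex))
  missing_sex <- setdiff(sexes, unique(data$sex))
  if (length(missing_sex) > 0L) {
    stop("fit_category_model: no data for sex: ", paste(missing_sex, collapse = ", "))
  }
  covs <- config$covariates
  if (length(covs) > 0L && !is.null(covariates)) {
    data <- dplyr::left_join(data, covariates[c("location", "year", covs)],
                             by = c("location", "year"))
    grid <- dplyr::left_join(grid, covariates[c("location", "year", covs)],
                             by = c("location", "year"))
  } else {
    covs <- character()
  }

  keys <- grid
  out <- matrix(NA_real_, nrow(keys), config$n_draws)
  for (si in seq_along(sexes)) {
    sx <- sexes[si]
    d <- data[data$sex == sx, ]
    g <- which(keys$sex == sx)
    local_rng(config$seed + si - 1L)
    out[g, ] <- fit_logit_surface(d, keys[g, , drop = FALSE], config, covs)
  }
  ds <- draw_surface(keys[setdiff(names(keys), config$covariates)], out)
  ds
}

# shared binomial-GAM machinery for prevalence and coverage surfaces
fit_logit_surface <- function(d, cells, config, covs) {
  d$age_mid <- age_mid_of(d$age_low)
  cells$age_mid <- age_mid_of(cells$age_low)
  use_re <- !is.null(config$random_effect) &&
    length(unique(d[[config$random_effect]])) > 1L
  if (use_re) {
    d$.re <- factor(d[[config$random_effect]])
    cells$.re <- factor(cells[[config$random_effect]], levels = levels(d$.re))
    if (anyNA(cells$.re)) stop("prediction cells contain unobserved random-effect levels")
  }
  n_age <- length(unique(d$age_mid))
  age_term <- if (n_age >= 4L) {
    sprintf("s(age_mid, k = %d)", min(config$df, n_age))
  } else if (n_age >= 2L) "age_mid" else NULL
  terms <- c(age_term, covs, if (use_re) "s(.re, bs = \"re\")", "1")
  keep_covs <- covs
  repeat {
    form <- stats::as.formula(paste("prevalence ~", paste(terms, collapse = " + ")))
    # quasibinomial: the Pearson dispersion inflates coefficient uncertainty
    # for non-sampling variance (design effects, residual heterogeneity)
    fit <- suppressWarnings(mgcv::gam(form, family = stats::quasibinomial(),
                                      weights = effective_sample_size,
                                      data = d, method = "REML"))
    if (!fit$converged) stop("fit_category_model: model did not converge (",
                             nrow(d), " rows)")
    bad <- violated_signs(fit, keep_covs, config$covariate_sign)
    if (length(bad) == 0L) break
    keep_covs <- setdiff(keep_covs, bad)
    terms <- setdiff(terms, bad)
  }
  beta <- stats::coef(fit)
  V <- stats::vcov(fit, unconditional = TRUE)
  draws_b <- MASS::mvrnorm(config$n_draws, beta, V)
  Xp <- stats::predict(fit, newdata = cells, type = "lpmatrix")
  eta <- Xp %*% t(draws_b)
  # residual between-cell heterogeneity: cell-level truth deviates from the
  # additive surface by more than sampling noise allows (non-sampling
  # variance). Estimate tau^2 by moments on the logit scale and add it to
  # the prediction draws, giving predictive rather than confidence intervals.
  tau <- logit_heterogeneity(d, fit)
  if (tau > 0) {
    eta <- eta + matrix(stats::rnorm(length(eta), 0, tau), nrow(eta), ncol(eta))
  }
  stats::plogis(eta)
}

# method-of-moments heterogeneity of observed logits around the fitted
# surface, net of binomial sampling variance (delta method)
logit_heterogeneity <- function(d, fit) {
  mu <- stats::fitted(fit)
  n <- d$effective_sample_size
  p_obs <- (d$prevalence * n + 0.5) / (n + 1)
  mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  r <- stats::qlogis(p_obs) - stats::qlogis(mu_c)
  v <- 1 / (n * mu_c * (1 - mu_c))
  tau2 <- mean(r^2 - v)
  if (!is.finite(tau2) || tau2 <= 0) return(0)
  sqrt(tau2)
}

violated_signs <- function(fit, covs, sign_spec) {
  if (is.null(sign_spec) || length(covs) == 0L) return(character())
  cf <- stats::coef(fit)
  bad <- character()
  for (v in intersect(covs, names(sign_spec))) {
    if (v %in% names(cf) && sign(cf[[v]]) * sign_spec[[v]] < 0) bad <- c(bad, v)
  }
  bad
}

#' Rescale the three top-level surfaces to sum to one
#'
#' Per cell and per draw, the normal, mild and moderate-plus surfaces are
#' divided by their three-way sum so that prevalence rates sum to one for
#' each age, year, sex and location.
#'
#' @param normal,mild,mod_plus [draw_surface()] objects on identical axes.
#' @return Named list of the three rescaled surfaces.
#' @export
squeeze_top_level <- function(normal, mild, mod_plus) {
  mild <- ds_align(mild, normal)
  mod_plus <- ds_align(mod_plus, normal)
  denom <- normal$draws + mild$draws + mod_plus$draws
  if (any(denom <= 0)) stop("squeeze_top_level: zero three-way sum in some cell/draw")
  list(normal = draw_surface(normal$keys, normal$draws / denom),
       mild = draw_surface(normal$keys, mild$draws / denom),
       mod_plus = draw_surface(normal$keys, mod_plus$draws / denom))
}

#' Rescale the five severity surfaces to the moderate-plus envelope
#'
#' Per cell and per draw, each severity surface is scaled by
#' `envelope / (five-way sum)` so the severities sum exactly to the
#' moderate-plus envelope. Where the envelope is zero the severities are
#' zero. Where all five sub-models are zero but the envelope is positive,
#' the envelope is distributed by the five models' global mean shares (a
#' warning reports the affected cell count).
#'
#' @param five_surfaces Named list of five [draw_surface()]s in severity
#'   order (moderate ... complete).
#' @param envelope Moderate-plus [draw_surface()] from [squeeze_top_level()].
#' @return Named list of five rescaled surfaces.
#' @export
squeeze_severities <- function(five_surfaces, envelope) {
  five_surfaces <- lapply(five_surfaces, ds_align, template = envelope)
  denom <- Reduce(`+`, lapply(five_surfaces, function(s) s$draws))
  degen <- denom == 0 & envelope$draws > 0
  scale <- envelope$draws / denom
  scale[denom == 0] <- 0
  out <- lapply(five_surfaces, function(s) {
    draw_surface(envelope$keys, s$draws * scale)
  })
  if (any(degen)) {
    warning("squeeze_severities: envelope positive but all sub-models zero in ",
            sum(degen), " cell/draw(s); distributed by global mean shares")
    tot <- sum(vapply(five_surfaces, function(s) mean(s$draws), 0))
    shares <- vapply(five_surfaces, function(s) mean(s$draws), 0) / tot
    if (!is.finite(tot) || tot <= 0) shares <- rep(1 / length(five_surfaces),
                                                   length(five_surfaces))
    for (i in seq_along(out)) {
      out[[i]]$draws[degen] <- envelope$draws[degen] * shares[i]
    }
  }
  out
}

#' Stack per-category surfaces into one surface with a category column
#'
#' @param surfaces Named list of [draw_surface()]s on identical axes; names
#'   become the `category` key level in the given order.
#' @return A single [draw_surface()] with a `category` key column.
#' @export
stack_categories <- function(surfaces) {
  nm <- names(surfaces)
  stopifnot(!is.null(nm), all(nzchar(nm)))
  template <- surfaces[[1]]
  surfaces <- lapply(surfaces, ds_align, template = template)
  keys <- dplyr::bind_rows(lapply(nm, function(n) {
    k <- surfaces[[n]]$keys
    k$category <- n
    k
  }))
  keys$category <- factor(keys$category, levels = nm)
  draw_surface(keys, do.call(rbind, lapply(surfaces, function(s) s$draws)))
}
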