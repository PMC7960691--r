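#' Fit the prevalence forecasting regression
#'
#' Sex-specific linear regression of logit prevalence rates on year, region,
#' a region-by-year interaction, and a cubic B-spline over age (knots at
#' the interior quintiles of the age grid). The regression is run once on
#' the observed rates and then `resamples` times on residual-bootstrap
#' replicates, yielding a coefficient draw set per sex; the logit scale
#' keeps every projected rate inside (0, 1).
#'
#' @param rates Tibble (region, sex, year, age_low, rate) of age-specific
#'   prevalence rates for the input years.
#' @param resamples Number of bootstrap refits (default 1000).
#' @param seed Integer seed.
#' @param spline_df Degrees of freedom of the cubic age spline.
#' @return List of class `forecast_model`: per-sex elements with the base
#'   fit, coefficient draw matrix, and the model frame metadata needed for
#'   prediction.
#' @export
fit_forecast <- function(rates, resamples = 1000L, seed = 1L, spline_df = 5L) {
  if (length(unique(rates$year)) < 2L) stop("fit_forecast: need >= 2 input years")
  if (length(unique(rates$region)) < 2L) {
    stop("fit_forecast: need >= 2 regions (design would be rank deficient)")
  }
  full <- tidyr::crossing(region = unique(rates$region), year = unique(rates$year))
  have <- dplyr::distinct(rates[c("region", "year")])
  if (nrow(dplyr::anti_join(full, have, by = c("region", "year"))) > 0L) {
    stop("fit_forecast: every region must be present in every input year")
  }
  local_rng(seed)
  eps <- 1e-6
  rates$y <- stats::qlogis(pmin(pmax(rates$rate, eps), 1 - eps))
  rates$age_mid <- age_mid_of(rates$age_low)
  rates$year_c <- rates$year - 2000
  knots <- unique(stats::quantile(rates$age_mid, probs = c(0.2, 0.4, 0.6, 0.8)))
  bounds <- range(rates$age_mid)

  fit_sex <- function(d) {
    fit <- stats::lm(y ~ region * year_c +
                       splines::bs(age_mid, knots = knots, degree = 3,
                                   Boundary.knots = bounds), data = d)
    X <- stats::model.matrix(fit)
    res <- stats::residuals(fit)
    fv <- stats::fitted(fit)
    XtXinvXt <- solve(crossprod(X), t(X))
    coefs <- matrix(NA_real_, resamples, ncol(X))
    for (b in seq_len(resamples)) {
      yb <- fv + sample(res, length(res), replace = TRUE)
      coefs[b, ] <- XtXinvXt %*% yb
    }
    colnames(coefs) <- colnames(X)
    list(fit = fit, coef_draws = coefs, regions = sort(unique(d$region)))
  }
  sexes <- sort(unique(rates$sex))
  models <- lapply(sexes, function(sx) fit_sex(rates[rates$sex == sx, ]))
  names(models) <- sexes
  structure(list(models = models, knots = knots, bounds = bounds,
                 resamples = as.integer(resamples), seed = as.integer(seed)),
            class = "forecast_model")
}

#' Project prevalence rates and case numbers to future years
#'
#' Per coefficient draw, predicted logit rates are inverted to the rate
#' scale, multiplied by forecasted population, and summed over ages to
#' regional case draws; global counts are the sum over regions per draw.
#' Rates below zero would be clipped with a count, but the logit scale
#' makes this vacuous (`clipped` is reported for the audit trail).
#'
#' @param model A [fit_forecast()] model.
#' @param years Projection years (e.g. 2030, 2040, 2050).
#' @param population_forecast Tibble (region, year, sex, age_low, pop)
#'   covering the requested years (location-level tables are summed).
#' @param age_lows Age groups to project (default those of the population).
#' @return List: `rates` (a [draw_surface()] keyed by region, year, sex,
#'   age_low), `cases` (a `burden_table` keyed by region and year, with a
#'   global row set), and `clipped` (count of clipped rate draws).
#' @export
project <- function(model, years, population_forecast,
                    age_lows = sort(unique(population_forecast$age_low))) {
  pop <- population_forecast
  if ("location" %in% names(pop)) {
    pop <- dplyr::summarise(dplyr::group_by(pop, .data$region, .data$year,
                                            .data$sex, .data$age_low),
                            pop = sum(.data$pop), .groups = "drop")
  }
  missing_years <- setdiff(years, unique(pop$year))
  if (length(missing_years) > 0L) {
    stop("project: population forecast missing years ",
         paste(missing_years, collapse = ", "))
  }
  out_rates <- list()
  clipped <- 0L
  for (sx in names(model$models)) {
    m <- model$models[[sx]]
    newd <- tidyr::crossing(region = m$regions, year = as.integer(years),
                            age_low = age_lows)
    newd$sex <- sx
    newd$age_mid <- age_mid_of(newd$age_low)
    newd$year_c <- newd$year - 2000
    Xp <- stats::model.matrix(stats::delete.response(stats::terms(m$fit)),
                              data = newd)
    eta <- Xp %*% t(m$coef_draws)
    p <- stats::plogis(eta)
    clipped <- clipped + sum(p < 0)
    p[p < 0] <- 0
    out_rates[[sx]] <- draw_surface(newd[c("region", "year", "sex", "age_low")], p)
  }
  rates <- draw_surface(
    dplyr::bind_rows(lapply(out_rates, function(s) s$keys)),
    do.call(rbind, lapply(out_rates, function(s) s$draws))
  )
  popv <- pop$pop[vctrs_match(rates$keys[c("region", "year", "sex", "age_low")],
                              pop[c("region", "year", "sex", "age_low")])]
  if (anyNA(popv)) stop("project: population forecast missing some strata")
  cases_cells <- draw_surface(rates$keys, rates$draws * popv)
  regional <- ds_sum_over(cases_cells, c("region", "year"))
  global <- ds_sum_over(cases_cells, "year")
  gkeys <- global$keys
  gkeys$region <- "global"
  cases <- structure(list(
    keys = dplyr::bind_rows(regional$keys, gkeys[c("region", "year")]),
    case_rate = NULL, yld_rate = NULL,
    cases = rbind(regional$draws, global$draws),
    ylds = rbind(regional$draws * 0, global$draws * 0)
  ), class = "burden_table")
  list(rates = rates, cases = cases, clipped = clipped)
}
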