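#' Years lived with disability from health-state prevalence
#'
#' YLD rate per person-year = prevalence x disability weight of the health
#' state; counts multiply rates by stratum population. Disability-weight
#' uncertainty is propagated (by default) by resampling one weight per
#' state and draw from a logit-normal matched to the published 95%
#' uncertainty interval, shared across all cells of a draw.
#'
#' @param state_surface A [draw_surface()] whose keys include `category`
#'   (severity), logical `ringing`, and the population keys `location`,
#'   `year`, `sex`, `age_low`.
#' @param dw_table A [disability_weights()] table.
#' @param population Tibble (location, year, sex, age_low, pop).
#' @param dw_uncertainty Resample weights per draw (default `TRUE`).
#' @param seed Seed for the weight resampling.
#' @return A list of class `burden_table`: `keys`, and draw matrices
#'   `case_rate`, `yld_rate`, `cases`, `ylds`.
#' @export
compute_ylds <- function(state_surface, dw_table = disability_weights(),
                         population, dw_uncertainty = TRUE, seed = 1L) {
  k <- state_surface$keys
  state <- health_state(as.character(k$category), k$ringing)
  idx <- match(state, dw_table$state)
  if (anyNA(idx)) {
    stop("compute_ylds: no disability weight for state(s): ",
         paste(unique(state[is.na(idx)]), collapse = ", "))
  }
  D <- n_draws(state_surface)
  if (dw_uncertainty) {
    local_rng(seed)
    dw_draws <- matrix(0, nrow(dw_table), D)
    nz <- which(dw_table$weight > 0)
    mu <- stats::qlogis(dw_table$weight[nz])
    sdv <- (stats::qlogis(dw_table$upper[nz]) - stats::qlogis(dw_table$lower[nz])) /
      (2 * stats::qnorm(0.975))
    dw_draws[nz, ] <- stats::plogis(matrix(stats::rnorm(length(nz) * D, mu, sdv),
                                           length(nz), D))
  } else {
    dw_draws <- matrix(dw_table$weight, nrow(dw_table), D)
  }
  yld_rate <- state_surface$draws * dw_draws[idx, , drop = FALSE]

  pop <- population$pop[vctrs_match(k[c("location", "year", "sex", "age_low")],
                                    population[c("location", "year", "sex", "age_low")])]
  if (anyNA(pop)) stop("compute_ylds: population missing for some strata")
  structure(list(keys = k,
                 case_rate = state_surface$draws,
                 yld_rate = yld_rate,
                 cases = state_surface$draws * pop,
                 ylds = yld_rate * pop),
            class = "burden_table")
}

#' @export
print.burden_table <- function(x, ...) {
  cat("<burden_table> ", nrow(x$keys), " strata x ", ncol(x$cases), " draws\n",
      sep = "")
  invisible(x)
}

#' Sum a burden table over strata at draw level
#'
#' Counts (cases, YLDs) are added draw by draw within groups before any
#' summarisation, so aggregate uncertainty intervals come from sums of
#' draws rather than sums of interval bounds.
#'
#' @param burden A [compute_ylds()] burden table.
#' @param by Key columns to retain.
#' @return A `burden_table` keyed by `by` (rates dropped: they are not
#'   additive across strata).
#' @export
burden_sum_over <- function(burden, by) {
  g <- do.call(paste, c(lapply(burden$keys[by], as.character), sep = "\r"))
  gi <- match(g, unique(g))
  keys <- burden$keys[!duplicated(gi), by, drop = FALSE]
  cases <- rowsum(burden$cases, gi, reorder = FALSE)
  ylds <- rowsum(burden$ylds, gi, reorder = FALSE)
  dimnames(cases) <- dimnames(ylds) <- NULL
  structure(list(keys = keys, case_rate = NULL, yld_rate = NULL,
                 cases = cases, ylds = ylds), class = "burden_table")
}

#' Aggregate a location-level burden table to regions and the globe
#'
#' @param burden A `burden_table` whose keys include `location`.
#' @param hierarchy Tibble (location, region) partitioning the locations.
#' @param by Additional key columns to retain (e.g. year, category).
#' @return A `burden_table` keyed by `region` (including a `"global"` row
#'   set) and `by`.
#' @export
aggregate_burden <- function(burden, hierarchy, by = setdiff(names(burden$keys),
                                                             c("location", "region"))) {
  idx <- match(burden$keys$location, hierarchy$location)
  if (anyNA(idx)) {
    stop("aggregate_burden: unmapped location(s): ",
         paste(unique(burden$keys$location[is.na(idx)]), collapse = ", "))
  }
  b <- burden
  b$keys$region <- hierarchy$region[idx]
  regional <- burden_sum_over(b, c("region", by))
  g <- b
  g$keys$region <- "global"
  global <- burden_sum_over(g, c("region", by))
  structure(list(keys = dplyr::bind_rows(regional$keys, global$keys),
                 case_rate = NULL, yld_rate = NULL,
                 cases = rbind(regional$cases, global$cases),
                 ylds = rbind(regional$ylds, global$ylds)),
            class = "burden_table")
}

#' Age-standardise a rate surface
#'
#' Weighted sum of age-specific rates with fixed standard-population
#' weights, computed at draw level.
#'
#' @param rates A [draw_surface()] of rates keyed by `age_low` plus other
#'   columns.
#' @param standard Tibble (age_low, weight); weights must sum to 1 and
#'   cover every age group of the surface (an error names missing groups).
#' @return A [draw_surface()] keyed by the non-age columns.
#' @export
age_standardize <- function(rates, standard) {
  stopifnot(abs(sum(standard$weight) - 1) < 1e-6)
  w <- standard$weight[match(rates$keys$age_low, standard$age_low)]
  if (anyNA(w)) stop("age_standardize: no standard weight for age group(s) ",
                     paste(unique(rates$keys$age_low[is.na(w)]), collapse = ", "))
  by <- setdiff(names(rates$keys), "age_low")
  # each group must contain the full standard age set
  cnt <- stats::aggregate(list(n = rates$keys$age_low),
                          by = rates$keys[by], FUN = length)
  if (any(cnt$n != nrow(standard))) {
    stop("age_standardize: some groups are missing age groups of the standard")
  }
  ds_sum_over(draw_surface(rates$keys, rates$draws * w), by)
}

#' Percentage change between two draw vectors
#'
#' Computed draw by draw as `100 * (b - a) / a`, then summarised with the
#' usual draw conventions, so the reported change is the mean of draw-level
#' changes (which can differ in the last digit from the change of the
#' point estimates; both are exposed).
#'
#' @param a,b Numeric draw vectors of equal length (baseline, comparison).
#' @return Named numeric: `mean`, `lower`, `upper`, and
#'   `point` (change of the draw means).
#' @export
percent_change <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a <= 0)) stop("percent_change: baseline draws must be positive")
  ch <- 100 * (b - a) / a
  s <- summarize_draws(ch)
  c(s, point = 100 * (mean(b) - mean(a)) / mean(a))
}

#' Regression of age-standardised YLD rates on the HAQ index
#'
#' Ordinary least squares of location-level age-standardised YLD rates on
#' the Healthcare Access and Quality index, reporting the share of
#' variation explained.
#'
#' @param data Tibble with columns `asr_yld` and `haq`, one row per
#'   location.
#' @return List: `slope`, `intercept`, `adj_r2`, `r2`, `fit` (the `lm`).
#' @export
haq_regression <- function(data) {
  if (nrow(data) < 3L) stop("haq_regression: need at least 3 locations")
  if (stats::sd(data$haq) == 0) stop("haq_regression: HAQ index is constant")
  fit <- stats::lm(asr_yld ~ haq, data = data)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
       adj_r2 = s$adj.r.squared, r2 = s$r.squared, fit = fit)
}

#' Severity-by-region report table (cases and age-standardised prevalence)
#'
#' Mirrors the layout of severity-split burden reporting: one row per
#' (aggregate category, region) with prevalent cases in millions and
#' age-standardised prevalence, each with 95% uncertainty intervals.
#' Cases are rounded to 0.1 million and rates to 0.1 percentage points for
#' display; unrounded values are retained in `cases_mean` etc. Because the
#' severity-specific draws were squeezed to the moderate-plus envelope,
#' the five severe categories sum to the moderate-plus aggregate by
#' construction at draw level.
#'
#' @param category_surface [draw_surface()] of category prevalence rates
#'   keyed by (location, year, sex, age_low, category).
#' @param population Population tibble.
#' @param hierarchy Tibble (location, region).
#' @param standard Standard population (age_low, weight).
#' @param year Reporting year.
#' @return Tibble with one row per category x region.
#' @export
report_severity_table <- function(category_surface, population, hierarchy,
                                  standard, year) {
  sel <- category_surface$keys$year == year
  surf <- draw_surface(category_surface$keys[sel, , drop = FALSE],
                       category_surface$draws[sel, , drop = FALSE])
  cats <- levels(factor(surf$keys$category))
  if (is.factor(surf$keys$category)) cats <- levels(surf$keys$category)
  sev5 <- setdiff(cats, c("normal", "mild"))

  # aggregate categories: all loss (>= 20 dB), moderate-plus (>= 35 dB)
  agg <- function(surf, members, label) {
    sub <- ds_filter(surf, as.character(category) %in% members)
    sub <- ds_sum_over(sub, setdiff(names(sub$keys), "category"))
    sub$keys$category <- label
    sub
  }
  pieces <- c(
    list(agg(surf, setdiff(cats, "normal"), "all_loss"),
         agg(surf, sev5, "mod_plus")),
    lapply(c("mild", sev5), function(cz) agg(surf, cz, cz))
  )
  rows <- lapply(pieces, function(p) {
    pop <- population$pop[vctrs_match(p$keys[c("location", "year", "sex", "age_low")],
                                      population[c("location", "year", "sex", "age_low")])]
    bt <- structure(list(keys = p$keys, cases = p$draws * pop, ylds = p$draws * 0),
                    class = "burden_table")
    reg <- aggregate_burden(bt, hierarchy, by = "category")
    cs <- summarize_draws(reg$cases)
    # age-standardised prevalence: population-weighted location rates within
    # region, then standard weights over age, at draw level
    p2 <- p
    p2$keys$region <- hierarchy$region[match(p$keys$location, hierarchy$location)]
    num <- ds_sum_over(draw_surface(p2$keys, p2$draws * pop),
                       c("region", "age_low", "category"))
    den <- rowsum(pop, paste(p2$keys$region, p2$keys$age_low), reorder = FALSE)
    gnum <- ds_sum_over(draw_surface(p2$keys, p2$draws * pop),
                        c("age_low", "category"))
    gden <- rowsum(pop, p2$keys$age_low, reorder = FALSE)
    ord <- match(paste(num$keys$region, num$keys$age_low), rownames(den))
    rate_reg <- draw_surface(num$keys, num$draws / as.vector(den)[ord])
    gord <- match(as.character(gnum$keys$age_low), rownames(gden))
    gkeys <- gnum$keys
    gkeys$region <- "global"
    rate_all <- draw_surface(dplyr::bind_rows(rate_reg$keys, gkeys),
                             rbind(rate_reg$draws,
                                   gnum$draws / as.vector(gden)[gord]))
    asr <- age_standardize(rate_all, standard)
    asr_s <- summarize_draws(asr$draws)
    ridx <- match(reg$keys$region, asr$keys$region)
    tibble::tibble(
      category = reg$keys$category, region = reg$keys$region,
      cases_mean = cs$mean, cases_lower = cs$lower, cases_upper = cs$upper,
      cases_millions = round(cs$mean / 1e6, 1),
      asr_mean = asr_s$mean[ridx], asr_lower = asr_s$lower[ridx],
      asr_upper = asr_s$upper[ridx],
      asr_pct = round(100 * asr_s$mean[ridx], 1)
    )
  })
  dplyr::bind_rows(rows)
}
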