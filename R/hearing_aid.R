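#' Tabulate hearing-aid coverage observations from microdata
#'
#' Coverage is the proportion of individuals at a given severity who use a
#' hearing aid. One row per (location, year, sex, age group, severity) with
#' user and total counts.
#'
#' @param records Microdata from [simulate_microdata()].
#' @return Tibble (location, year, sex, age_low, severity, users, total).
#' @export
tabulate_coverage <- function(records) {
  imp <- records[records$severity != "normal", ]
  dplyr::summarise(
    dplyr::group_by(imp, .data$location, .data$year, .data$sex, .data$age_low,
                    .data$severity),
    users = sum(.data$uses_hearing_aid), total = dplyr::n(), .groups = "drop")
}

#' Fit severity-specific hearing-aid coverage surfaces
#'
#' One binomial spline model per severity (same surrogate machinery as the
#' prevalence models, sexes pooled into a single fit with a sex term
#' folded into the grid via separate per-sex fits). Severities with no
#' observations borrow the surface of the nearest observed lower severity
#' (or the nearest higher one at the bottom), and a severity-gradient prior
#' is enforced by a running maximum across severities per cell and draw, so
#' coverage is non-decreasing in severity.
#'
#' @param data Coverage observations from [tabulate_coverage()].
#' @param config A [model_config()]; the default drops covariates.
#' @param grid Prediction cells (location, year, sex, age_low).
#' @param covariates Optional covariate tibble if the config lists any.
#' @param scheme A [severity_scheme()].
#' @return A [draw_surface()] keyed by grid columns plus `severity`,
#'   including a zero-coverage `normal` level.
#' @export
fit_coverage <- function(data, config = model_config(covariates = NULL),
                         grid = NULL, covariates = NULL,
                         scheme = severity_scheme()) {
  if (sum(data$total) <= 0) stop("fit_coverage: all observations have zero sample size")
  sev <- severity_levels(scheme, loss_only = TRUE)
  if (is.null(grid)) {
    grid <- tidyr::crossing(dplyr::distinct(data[c("location", "year")]),
                            sex = sort(unique(data$sex)),
                            age_low = sort(unique(data$age_low)))
  }
  observed <- sev[sev %in% as.character(data$severity[data$total > 0])]
  if (length(observed) == 0L) stop("fit_coverage: no severity has observations")

  per_sev <- list()
  for (s in observed) {
    d <- data[as.character(data$severity) == s & data$total > 0, ]
    d$prevalence <- d$users / d$total
    d$effective_sample_size <- d$total
    per_sev[[s]] <- fit_category_model(d, config, covariates = covariates,
                                       grid = grid)
  }
  # borrow for unobserved severities from the nearest observed category
  for (i in seq_along(sev)) {
    s <- sev[i]
    if (!is.null(per_sev[[s]])) next
    lower <- rev(sev[seq_len(i - 1L)])
    src <- c(lower[lower %in% observed], sev[-seq_len(i)][sev[-seq_len(i)] %in% observed])[1]
    per_sev[[s]] <- per_sev[[src]]
  }
  per_sev <- per_sev[sev]

  # severity-gradient prior: running maximum across increasing severity
  for (i in seq_along(per_sev)[-1]) {
    aligned <- ds_align(per_sev[[i]], per_sev[[1]])
    prev_d <- ds_align(per_sev[[i - 1L]], per_sev[[1]])$draws
    per_sev[[i]] <- draw_surface(per_sev[[1]]$keys, pmax(aligned$draws, prev_d))
  }
  normal <- draw_surface(per_sev[[1]]$keys,
                         matrix(0, nrow(per_sev[[1]]$keys), n_draws(per_sev[[1]])))
  stack_categories(c(list(normal = normal), per_sev))
}

#' Shift aided individuals one severity category down
#'
#' For each severity from mild upward, the proportion of individuals using
#' a hearing aid is moved to the category directly below; aided mild cases
#' count as normal hearing in the adjusted estimates. All outflows are
#' computed from the unadjusted values simultaneously (a single
#' reclassification, no cascading), so the all-category sum is conserved
#' per cell and draw. The result is marked `aid_adjusted` and a second
#' application errors: the adjustment is applied exactly once.
#'
#' @param prevalence A [draw_surface()] over all categories (key column
#'   `category`), normalised to sum to one per cell.
#' @param coverage A coverage [draw_surface()] from [fit_coverage()] (key
#'   column `category` or `severity`); values in \[0, 1\].
#' @return Adjusted [draw_surface()] with attribute `aid_adjusted = TRUE`.
#' @export
apply_aid_shift <- function(prevalence, coverage) {
  if (isTRUE(attr(prevalence, "aid_adjusted"))) {
    stop("apply_aid_shift: surface is already hearing-aid adjusted")
  }
  if (any(coverage$draws < 0 | coverage$draws > 1)) {
    stop("apply_aid_shift: coverage values outside [0, 1]")
  }
  ckeys <- coverage$keys
  if (!"category" %in% names(ckeys) && "severity" %in% names(ckeys)) {
    names(ckeys)[names(ckeys) == "severity"] <- "category"
    coverage <- draw_surface(ckeys, coverage$draws)
  }
  cats <- if (is.factor(prevalence$keys$category)) {
    levels(prevalence$keys$category)
  } else {
    # fall back to the default scheme's severity order
    intersect(severity_levels(), unique(prevalence$keys$category))
  }
  coverage <- ds_align(coverage, prevalence)
  out <- prevalence$draws
  cat_chr <- as.character(prevalence$keys$category)
  base_keys <- prevalence$keys[setdiff(names(prevalence$keys), "category")]
  cell_id <- do.call(paste, c(lapply(base_keys, as.character), sep = "\r"))
  for (i in seq_along(cats)[-1]) {
    rows_i <- which(cat_chr == cats[i])
    rows_below <- which(cat_chr == cats[i - 1L])
    rows_below <- rows_below[match(cell_id[rows_i], cell_id[rows_below])]
    outflow <- prevalence$draws[rows_i, , drop = FALSE] *
      coverage$draws[rows_i, , drop = FALSE]
    out[rows_i, ] <- out[rows_i, ] - outflow
    out[rows_below, ] <- out[rows_below, ] + outflow
  }
  res <- draw_surface(prevalence$keys, out)
  attr(res, "aid_adjusted") <- TRUE
  res
}
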