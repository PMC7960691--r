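#' Meta-regression of the female/male prevalence ratio
#'
#' Fits, per age group, an inverse-variance weighted trimmed random-effects
#' mean of the log female/male prevalence ratio across studies reporting
#' both sexes separately. This is the documented surrogate for a
#' regularised, trimmed Bayesian meta-regression: trimming drops the
#' `trim` fraction of pairs with the largest absolute standardised
#' residuals from a provisional pooled mean, and the remaining pairs are
#' pooled with a DerSimonian-Laird random-effects model.
#'
#' @param paired_data Prevalence rows with `sex` in `{"female","male"}`
#'   reported separately for the same (location, year, age band, dB range).
#' @param trim Fraction of pairs trimmed (default 0.10).
#' @param by_age Pool within age groups (`TRUE`, with a pooled fallback for
#'   age groups with fewer than 2 pairs) or across all ages.
#' @return A list of class `sex_ratio_model` with per-age-group tibble
#'   `estimates` (columns `age_low`, `log_ratio`, `se`, `tau2`, `n_pairs`)
#'   and a `pooled` row used as fallback.
#' @export
fit_sex_ratio <- function(paired_data, trim = 0.10, by_age = TRUE) {
  stopifnot(trim >= 0, trim < 0.5)
  f <- paired_data[paired_data$sex == "female", ]
  m <- paired_data[paired_data$sex == "male", ]
  key <- c("location", "year", "age_low", "age_high", "db_low", "db_high")
  pairs <- dplyr::inner_join(f, m, by = key, suffix = c("_f", "_m"))
  pairs <- pairs[pairs$prevalence_f > 0 & pairs$prevalence_m > 0, ]
  if (nrow(pairs) < 2L) {
    stop("fit_sex_ratio: fewer than 2 usable female/male pairs")
  }
  pairs$yi <- log(pairs$prevalence_f / pairs$prevalence_m)
  # delta-method variance of log(p) for a binomial proportion
  vlog <- function(p, n) pmax((1 - p) / (p * n), 1e-8)
  pairs$vi <- vlog(pairs$prevalence_f, pairs$effective_sample_size_f) +
    vlog(pairs$prevalence_m, pairs$effective_sample_size_m)

  pool_one <- function(d) {
    d <- trim_pairs(d, trim)
    if (nrow(d) <= 2000L) {
      fit <- metafor::rma(yi = d$yi, vi = d$vi, method = "DL")
      return(tibble::tibble(log_ratio = as.numeric(fit$beta), se = fit$se,
                            tau2 = fit$tau2, n_pairs = nrow(d)))
    }
    # metafor::rma materialises k x k matrices; above typical meta-analysis
    # sizes use the closed-form DerSimonian-Laird estimate (same formulas)
    w <- 1 / d$vi
    mu <- sum(w * d$yi) / sum(w)
    q <- sum(w * (d$yi - mu)^2)
    cc <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (nrow(d) - 1L)) / cc)
    ws <- 1 / (d$vi + tau2)
    tibble::tibble(log_ratio = sum(ws * d$yi) / sum(ws),
                   se = sqrt(1 / sum(ws)), tau2 = tau2, n_pairs = nrow(d))
  }
  pooled <- pool_one(pairs)
  pooled$age_low <- NA_integer_

  estimates <- NULL
  if (by_age) {
    grps <- split(pairs, pairs$age_low)
    ok <- vapply(grps, function(d) nrow(d) >= 2L, TRUE)
    if (any(ok)) {
      estimates <- dplyr::bind_rows(lapply(names(grps)[ok], function(a) {
        e <- pool_one(grps[[a]])
        e$age_low <- as.integer(a)
        e
      }))
    }
  }
  structure(list(estimates = estimates, pooled = pooled, trim = trim),
            class = "sex_ratio_model")
}

trim_pairs <- function(d, trim) {
  n_drop <- floor(trim * nrow(d))
  if (n_drop == 0L) return(d)
  w <- 1 / d$vi
  mu0 <- sum(w * d$yi) / sum(w)
  resid <- abs(d$yi - mu0) / sqrt(d$vi)
  keep <- order(resid)[seq_len(nrow(d) - n_drop)]
  d[keep, , drop = FALSE]
}

sex_ratio_lookup <- function(model, age_low) {
  est <- model$estimates
  if (!is.null(est)) {
    hit <- match(age_low, est$age_low)
    if (!is.na(hit)) return(est[hit, ])
  }
  model$pooled
}

#' Split a both-sex prevalence row into female and male rows
#'
#' Solves the two-equation system: female/male prevalence ratio equals the
#' modelled ratio, and the population-weighted mean of the two outputs
#' equals the input prevalence (so expected case counts are conserved).
#' Effective sample size is apportioned by population share and the
#' standard error is inflated by the ratio-model uncertainty (delta
#' method, heterogeneity added in quadrature).
#'
#' @param datum One prevalence row with `sex == "both"`.
#' @param model A [fit_sex_ratio()] model.
#' @param population Population tibble (location, year, sex, age_low, pop).
#' @return Tibble of two rows (female, male) in the input schema.
#' @export
apply_sex_split <- function(datum, model, population) {
  stopifnot(nrow(datum) == 1L, datum$sex == "both")
  pop <- population[population$location == datum$location &
                      population$year == datum$year &
                      population$age_low >= datum$age_low &
                      population$age_low < datum$age_high, ]
  pop_f <- sum(pop$pop[pop$sex == "female"])
  pop_m <- sum(pop$pop[pop$sex == "male"])
  if (pop_f + pop_m <= 0) stop("apply_sex_split: zero population in stratum")
  est <- sex_ratio_lookup(model, datum$age_low)
  ratio <- exp(est$log_ratio)
  p_m <- datum$prevalence * (pop_f + pop_m) / (pop_f * ratio + pop_m)
  p_f <- ratio * p_m
  se_infl <- sqrt(est$se^2 + est$tau2)
  out <- dplyr::bind_rows(datum, datum)
  out$sex <- c("female", "male")
  out$prevalence <- pmin(1, c(p_f, p_m))
  shares <- c(pop_f, pop_m) / (pop_f + pop_m)
  out$effective_sample_size <- datum$effective_sample_size * shares
  # deflate ESS further for the ratio-model uncertainty: an SE inflation by
  # factor k on the log scale behaves like dividing the sample size by k^2
  out$effective_sample_size <- out$effective_sample_size / (1 + se_infl^2 *
    out$prevalence * out$effective_sample_size / pmax(1 - out$prevalence, 1e-6))
  out
}

#' Severity-threshold crosswalk from individual-level audiometry
#'
#' Estimates, for each (alternative dB range, reference dB range) pair, the
#' mean logit difference between the prevalence under the alternative and
#' reference definitions across age-sex cells of the microdata, with its
#' standard error across cells. Cells where either prevalence is 0 or 1 are
#' excluded (logit undefined) with a count attached.
#'
#' @param microdata Audiometry records ([simulate_microdata()] schema).
#' @param alternative_ranges List of `c(db_low, db_high)` alternative ranges.
#' @param reference_ranges Matching list of reference ranges (defaults to
#'   the moderate-plus envelope for every alternative).
#' @param scheme A [severity_scheme()].
#' @return A tibble of class `crosswalk_model`: one row per range pair with
#'   `coefficient` (mean logit difference), `se`, `n_cells`, `n_excluded`.
#' @export
fit_crosswalk <- function(microdata, alternative_ranges,
                          reference_ranges = rep(list(c(35, Inf)),
                                                 length(alternative_ranges)),
                          scheme = severity_scheme()) {
  stopifnot(length(alternative_ranges) == length(reference_ranges))
  cell_prev <- function(r) {
    aff <- microdata$better_ear_pta >= r[1] & microdata$better_ear_pta < r[2]
    agg <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(sex = microdata$sex,
                                     age_low = microdata$age_low, aff = aff),
                      .data$sex, .data$age_low),
      p = mean(.data$aff), n = dplyr::n(), .groups = "drop")
    agg
  }
  rows <- lapply(seq_along(alternative_ranges), function(i) {
    ra <- alternative_ranges[[i]]
    rr <- reference_ranges[[i]]
    a <- cell_prev(ra)
    b <- cell_prev(rr)
    cells <- dplyr::inner_join(a, b, by = c("sex", "age_low"),
                               suffix = c("_alt", "_ref"))
    usable <- cells$p_alt > 0 & cells$p_alt < 1 & cells$p_ref > 0 & cells$p_ref < 1
    n_exc <- sum(!usable)
    cells <- cells[usable, ]
    if (nrow(cells) == 0L) {
      stop("fit_crosswalk: all cells excluded for range [",
           ra[1], ",", ra[2], ")")
    }
    diffs <- stats::qlogis(cells$p_alt) - stats::qlogis(cells$p_ref)
    tibble::tibble(
      alt_low = ra[1], alt_high = ra[2], ref_low = rr[1], ref_high = rr[2],
      coefficient = mean(diffs),
      se = if (nrow(cells) > 1L) stats::sd(diffs) / sqrt(nrow(cells)) else 0,
      n_cells = nrow(cells), n_excluded = n_exc
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("crosswalk_model", class(out))
  out
}

#' Adjust an alternative-definition row to the reference definition
#'
#' Applies `inverse-logit(logit(p) - coefficient)` and flags the row as
#' reference. Prevalences of exactly 0 or 1 receive the half-case
#' continuity correction `p <- (x + 0.5) / (n + 1)` before the logit.
#' Uncertainty is inflated through the effective sample size by the
#' coefficient's standard error (delta method on the logit scale).
#'
#' @param datum One or more alternative-definition prevalence rows.
#' @param model A [fit_crosswalk()] model covering the rows' range pairs.
#' @return The rows mapped to the reference definition.
#' @export
apply_crosswalk <- function(datum, model) {
  idx <- match(paste(datum$db_low, datum$db_high),
               paste(model$alt_low, model$alt_high))
  if (anyNA(idx)) {
    stop("apply_crosswalk: no coefficient for range [",
         datum$db_low[which(is.na(idx))[1]], ",",
         datum$db_high[which(is.na(idx))[1]], ")")
  }
  p <- datum$prevalence
  n <- datum$effective_sample_size
  bad <- p <= 0 | p >= 1
  p[bad] <- (p[bad] * n[bad] + 0.5) / (n[bad] + 1)
  out <- datum
  out$prevalence <- stats::plogis(stats::qlogis(p) - model$coefficient[idx])
  out$db_low <- model$ref_low[idx]
  out$db_high <- model$ref_high[idx]
  out$definition <- "reference"
  se2 <- model$se[idx]^2
  out$effective_sample_size <- n / (1 + se2 * out$prevalence *
                                      (1 - out$prevalence) * n)
  out
}

#' Split wide age bands using a relative age pattern
#'
#' Rows spanning more than `max_span` years are split into 5-year groups
#' with output prevalences proportional to the supplied global age pattern
#' and constrained so the population-weighted mean of the outputs equals
#' the input prevalence (expected case counts are conserved). Sample size
#' is apportioned by population share. Rows at or under the span threshold
#' pass through unchanged.
#'
#' @param datum One prevalence row.
#' @param age_pattern Tibble (age_low, rel_prev), positive on the span.
#' @param population Population tibble (location, year, sex, age_low, pop).
#' @param max_span Threshold span in years (default 20; spans strictly
#'   greater are split).
#' @return Tibble of 5-year rows (or the input row unchanged).
#' @export
age_split <- function(datum, age_pattern, population, max_span = 20) {
  stopifnot(nrow(datum) == 1L)
  span <- datum$age_high - datum$age_low
  if (span <= max_span) return(datum)
  ages <- seq(datum$age_low, datum$age_high - 1, by = 5)
  pat <- age_pattern$rel_prev[match(ages, age_pattern$age_low)]
  if (anyNA(pat) || any(pat <= 0)) {
    stop("age_split: age pattern missing or non-positive on the span")
  }
  sexes <- if (datum$sex == "both") c("female", "male") else datum$sex
  pop <- population[population$location == datum$location &
                      population$year == datum$year &
                      population$sex %in% sexes &
                      population$age_low %in% ages, ]
  pop <- stats::aggregate(pop ~ age_low, data = pop, FUN = sum)
  popw <- pop$pop[match(ages, pop$age_low)]
  if (anyNA(popw) || sum(popw) <= 0) stop("age_split: population missing on the span")
  # scale k solves sum(w_a * k * pat_a) = p with w_a population shares
  w <- popw / sum(popw)
  k <- datum$prevalence / sum(w * pat)
  out <- datum[rep(1L, length(ages)), ]
  out$age_low <- ages
  out$age_high <- ages + 5
  out$prevalence <- pmin(1, k * pat)
  out$effective_sample_size <- datum$effective_sample_size * w
  out
}

#' Harmonise a mixed survey table to the reference definition
#'
#' Applies, in order: severity crosswalk to alternative-definition rows,
#' sex split to both-sex rows, and age split to wide age bands. Rows that
#' are already reference, sex-specific and in 5-year bands pass through
#' unchanged (the pipeline is idempotent on harmonised data).
#'
#' @param data Survey prevalence rows ([tabulate_survey()] schema).
#' @param sex_model A [fit_sex_ratio()] model (or `NULL` if no both rows).
#' @param crosswalk A [fit_crosswalk()] model (or `NULL` if none needed).
#' @param age_pattern,population See [age_split()] / [apply_sex_split()].
#' @param max_span Age-split threshold.
#' @return Harmonised tibble of reference-definition, sex-specific rows.
#' @export
process_survey_data <- function(data, sex_model = NULL, crosswalk = NULL,
                                age_pattern = NULL, population = NULL,
                                max_span = 20) {
  alt <- data$definition == "alternative"
  if (any(alt)) {
    if (is.null(crosswalk)) stop("alternative-definition rows but no crosswalk model")
    data <- dplyr::bind_rows(data[!alt, ], apply_crosswalk(data[alt, ], crosswalk))
  }
  rows <- split(data, seq_len(nrow(data)))
  out <- lapply(rows, function(d) {
    if (d$sex == "both") {
      if (is.null(sex_model)) stop("both-sex rows but no sex-ratio model")
      d <- apply_sex_split(d, sex_model, population)
    }
    dplyr::bind_rows(lapply(split(d, seq_len(nrow(d))), age_split,
                            age_pattern = age_pattern, population = population,
                            max_span = max_span))
  })
  dplyr::bind_rows(out)
}
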