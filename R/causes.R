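#' Empirical cause-specific prevalence surfaces from microdata
#'
#' Builds, for each underlying cause (congenital birth defects, chronic
#' otitis media, meningitis, age-related and other), an unscaled prevalence
#' surface per (location, year, sex, age group, severity). The cause mix
#' among the impaired is estimated per age group, pooled over strata and
#' severities (the cause mixture is assumed to vary with age but not with
#' severity, mirroring the identical-across-causes assumption used for
#' tinnitus), with Dirichlet draws under a Jeffreys half-count prior; the
#' mix multiplies the stratum's empirical severity-specific prevalence
#' (half-case continuity, mean-preserving lognormal draws), giving strictly
#' positive surfaces for [attribute_causes()].
#'
#' @param records Microdata from [simulate_microdata()].
#' @param grid Cells (location, year, sex, age_low) to cover; defaults to
#'   those present in the records.
#' @param n_draws,seed Draw count and seed.
#' @param scheme A [severity_scheme()].
#' @return Named list of [draw_surface()]s, one per cause, keyed by the
#'   grid columns plus `category`.
#' @export
estimate_cause_models <- function(records, grid = NULL, n_draws = 1000L,
                                  seed = 1L, scheme = severity_scheme()) {
  local_rng(seed)
  causes <- c("congenital", "otitis_media", "meningitis", "age_other")
  sev <- severity_levels(scheme, loss_only = TRUE)
  if (is.null(grid)) {
    grid <- dplyr::distinct(records[c("location", "year", "sex", "age_low")])
  }
  keys <- tidyr::crossing(grid, category = factor(sev, levels = sev))
  imp <- records[records$severity != "normal", ]

  # age-specific cause mixture: Dirichlet draws from pooled cause counts
  ages <- sort(unique(keys$age_low))
  frac_draws <- list()
  for (cz in causes) frac_draws[[cz]] <- matrix(NA_real_, length(ages), n_draws)
  for (ai in seq_along(ages)) {
    cnt <- table(factor(imp$cause[imp$age_low == ages[ai]], levels = causes))
    gam <- matrix(stats::rgamma(length(causes) * n_draws,
                                shape = as.numeric(cnt) + 0.5),
                  length(causes), n_draws)
    gam <- sweep(gam, 2L, colSums(gam), `/`)
    for (ci in seq_along(causes)) frac_draws[[causes[ci]]][ai, ] <- gam[ci, ]
  }

  # empirical severity prevalence per stratum with half-case continuity
  n_tab <- dplyr::summarise(
    dplyr::group_by(records, .data$location, .data$year, .data$sex, .data$age_low),
    n = dplyr::n(), .groups = "drop")
  x_tab <- dplyr::summarise(
    dplyr::group_by(imp, .data$location, .data$year, .data$sex, .data$age_low,
                    category = .data$severity),
    x = dplyr::n(), .groups = "drop")
  tab <- dplyr::left_join(keys, x_tab,
                          by = c("location", "year", "sex", "age_low", "category"))
  tab <- dplyr::left_join(tab, n_tab, by = c("location", "year", "sex", "age_low"))
  tab$x[is.na(tab$x)] <- 0L
  tab$n[is.na(tab$n)] <- max(n_tab$n)
  p <- (tab$x + 0.5) / (tab$n + 2)
  se <- sqrt(p * (1 - p) / tab$n)
  sig <- sqrt(log1p((se / p)^2))
  prev_draws <- p * exp(matrix(stats::rnorm(nrow(tab) * n_draws), nrow(tab),
                               n_draws) * sig -
                          matrix(sig^2 / 2, nrow(tab), n_draws))
  age_idx <- match(tab$age_low, ages)
  out <- list()
  for (cz in causes) {
    out[[cz]] <- draw_surface(tab[c(names(grid), "category")],
                              prev_draws * frac_draws[[cz]][age_idx, , drop = FALSE])
  }
  out
}

#' Attribute severity-specific prevalence to underlying causes
#'
#' Below the age cutoff (default 20 years) the cause-specific surfaces are
#' proportionally rescaled, per severity, so they sum to the total
#' prevalence of that severity. At and above the cutoff the named causes
#' (otitis media, meningitis, congenital) are kept as supplied and the
#' residual is assigned to age-related and other hearing loss; a negative
#' residual (named causes exceeding the total) is handled by rescaling the
#' named causes to the total and setting the residual to zero, with the
#' affected cell/draw count reported in a warning and in the
#' `negative_residuals` attribute.
#'
#' @param severity_prev A [draw_surface()] of severity prevalence with a
#'   `category` key column (loss categories only, or including `normal`,
#'   which is ignored).
#' @param cause_models Named list of unscaled cause [draw_surface()]s from
#'   [estimate_cause_models()] (must include `age_other`).
#' @param age_cutoff Years; strata with `age_low < age_cutoff` use the
#'   scaling rule, others the residual rule.
#' @return A [draw_surface()] with an additional `cause` key column; per
#'   cell, the causes sum to the input severity prevalence.
#' @export
attribute_causes <- function(severity_prev, cause_models, age_cutoff = 20) {
  named <- setdiff(names(cause_models), "age_other")
  stopifnot("age_other" %in% names(cause_models), length(named) >= 1L)
  prev <- severity_prev
  if ("category" %in% names(prev$keys)) {
    keep <- as.character(prev$keys$category) != "normal"
    prev <- draw_surface(prev$keys[keep, , drop = FALSE],
                         prev$draws[keep, , drop = FALSE])
  }
  cm <- lapply(cause_models, ds_align, template = prev)
  if (any(vapply(cm, function(s) any(s$draws < 0), TRUE))) {
    stop("attribute_causes: cause model values must be >= 0")
  }
  young <- prev$keys$age_low < age_cutoff
  total <- prev$draws
  n_neg <- 0L
  out <- list()

  sum_named <- Reduce(`+`, lapply(cm[named], function(s) s$draws))
  sum_all <- sum_named + cm$age_other$draws
  # below the cutoff: proportional squeeze of all four causes to the total
  if (any(young)) {
    bad <- sum_all[young, , drop = FALSE] == 0 & total[young, , drop = FALSE] > 0
    if (any(bad)) {
      stop("attribute_causes: all-cause sum zero where total prevalence positive (",
           sum(bad), " cell/draws below the cutoff)")
    }
  }
  scale_young <- total / sum_all
  scale_young[sum_all == 0] <- 0
  # above the cutoff: residual rule, rescaling on negative residuals
  residual <- total - sum_named
  neg <- !young & residual < 0
  n_neg <- sum(neg)
  scale_named_old <- total / sum_named
  scale_named_old[sum_named == 0] <- 0

  for (cz in names(cm)) {
    d <- cm[[cz]]$draws
    res <- matrix(0, nrow(d), ncol(d))
    res[young, ] <- d[young, , drop = FALSE] * scale_young[young, , drop = FALSE]
    if (cz == "age_other") {
      r <- residual
      r[r < 0] <- 0
      res[!young, ] <- r[!young, , drop = FALSE]
    } else {
      keepv <- d
      keepv[neg] <- (d * scale_named_old)[neg]
      res[!young, ] <- keepv[!young, , drop = FALSE]
    }
    keys <- prev$keys
    keys$cause <- cz
    out[[cz]] <- draw_surface(keys, res)
  }
  if (n_neg > 0L) {
    warning("attribute_causes: negative residual above the cutoff in ", n_neg,
            " cell/draw(s); named causes rescaled to the total")
  }
  keys <- dplyr::bind_rows(lapply(out, function(s) s$keys))
  res <- draw_surface(keys, do.call(rbind, lapply(out, function(s) s$draws)))
  attr(res, "negative_residuals") <- n_neg
  res
}
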