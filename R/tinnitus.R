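#' Estimate tinnitus proportions among the hearing impaired
#'
#' Binomial proportion of impaired respondents (better-ear PTA at or above
#' 20 dB) reporting ringing, per (severity, age group, sex). Sparse strata
#' are pooled upward in a documented order: first over sex, then over
#' increasingly wide age windows within severity, finally to the severity
#' total. Records below 20 dB never enter a denominator.
#'
#' @param records Microdata from [simulate_microdata()].
#' @param scheme A [severity_scheme()].
#' @param min_n Minimum denominator before pooling is triggered.
#' @return Tibble of class `tinnitus_proportions`: columns `severity`,
#'   `age_low`, `sex`, `numerator`, `denominator`, `proportion`, `se`,
#'   `pooling` (level used).
#' @export
estimate_tinnitus <- function(records, scheme = severity_scheme(), min_n = 25L) {
  imp <- records[records$better_ear_pta >= 20, ]
  if (nrow(imp) == 0L) stop("estimate_tinnitus: no impaired records")
  sev <- severity_levels(scheme, loss_only = TRUE)
  imp$severity <- factor(as.character(imp$severity), levels = sev)

  base <- dplyr::summarise(
    dplyr::group_by(imp, .data$severity, .data$age_low, .data$sex),
    numerator = sum(.data$tinnitus), denominator = dplyr::n(), .groups = "drop")
  full <- tidyr::crossing(severity = factor(sev, levels = sev),
                          age_low = sort(unique(records$age_low)),
                          sex = sort(unique(records$sex)))
  tab <- dplyr::left_join(full, base, by = c("severity", "age_low", "sex"))
  tab$numerator[is.na(tab$numerator)] <- 0L
  tab$denominator[is.na(tab$denominator)] <- 0L
  tab$pooling <- "stratum"

  # pooling level 1: over sex
  bysexless <- dplyr::summarise(
    dplyr::group_by(base, .data$severity, .data$age_low),
    numerator = sum(.data$numerator), denominator = sum(.data$denominator),
    .groups = "drop")
  sparse <- tab$denominator < min_n
  idx <- match(paste(tab$severity, tab$age_low),
               paste(bysexless$severity, bysexless$age_low))
  rep1 <- sparse & !is.na(idx) & bysexless$denominator[idx] >= min_n
  tab$numerator[rep1] <- bysexless$numerator[idx[rep1]]
  tab$denominator[rep1] <- bysexless$denominator[idx[rep1]]
  tab$pooling[rep1] <- "sex-pooled"

  # pooling level 2: widening age windows within severity (both sexes)
  still <- which(tab$denominator < min_n)
  for (i in still) {
    s <- tab$severity[i]
    a <- tab$age_low[i]
    for (halfwidth in c(5, 10, 20, 40, 100)) {
      win <- bysexless[bysexless$severity == s &
                         abs(bysexless$age_low - a) <= halfwidth, ]
      if (sum(win$denominator) >= min_n) {
        tab$numerator[i] <- sum(win$numerator)
        tab$denominator[i] <- sum(win$denominator)
        tab$pooling[i] <- sprintf("age-window %d", halfwidth)
        break
      }
    }
  }
  # pooling level 3: severity total
  still <- which(tab$denominator < min_n)
  if (length(still) > 0L) {
    sevtot <- dplyr::summarise(dplyr::group_by(base, .data$severity),
                               numerator = sum(.data$numerator),
                               denominator = sum(.data$denominator),
                               .groups = "drop")
    j <- match(tab$severity[still], sevtot$severity)
    has <- !is.na(j) & sevtot$denominator[j] > 0
    tab$numerator[still[has]] <- sevtot$numerator[j[has]]
    tab$denominator[still[has]] <- sevtot$denominator[j[has]]
    tab$pooling[still[has]] <- "severity-pooled"
  }
  if (any(tab$denominator == 0L)) {
    # final fallback: all impaired records
    tot_n <- sum(base$numerator)
    tot_d <- sum(base$denominator)
    z <- tab$denominator == 0L
    tab$numerator[z] <- tot_n
    tab$denominator[z] <- tot_d
    tab$pooling[z] <- "overall"
  }

  p_raw <- tab$numerator / tab$denominator
  edge <- p_raw <= 0 | p_raw >= 1
  p_se <- p_raw
  p_se[edge] <- (tab$numerator[edge] + 0.5) / (tab$denominator[edge] + 1)
  tab$proportion <- p_raw
  tab$se <- sqrt(p_se * (1 - p_se) / tab$denominator)
  class(tab) <- c("tinnitus_proportions", class(tab))
  tab
}

#' Split a prevalence surface into with- and without-ringing health states
#'
#' Applies the tinnitus proportion `t` of each (severity, age group, sex)
#' stratum: with-ringing prevalence is `p * t` and without-ringing is
#' `p * (1 - t)`, with the same `t` across causes. Uncertainty in `t`
#' propagates by sampling one `t` per draw and stratum from its normal
#' approximation, truncated to \[0, 1\].
#'
#' @param surface A [draw_surface()] with key columns including `category`
#'   (severity), `age_low` and `sex` (a cause column, if present, is
#'   carried through unchanged).
#' @param proportions An [estimate_tinnitus()] table covering every
#'   (severity, age group, sex) present in the surface.
#' @param seed Seed for the per-draw proportion sampling; `NULL` applies
#'   the point proportions without resampling.
#' @return A [draw_surface()] with an additional logical `ringing` key; the
#'   two states sum to the input surface per cell and draw.
#' @export
split_by_tinnitus <- function(surface, proportions, seed = 1L) {
  k <- surface$keys
  sev_col <- if ("category" %in% names(k)) "category" else "severity"
  strat <- paste(as.character(k[[sev_col]]), k$age_low, k$sex)
  ptab <- proportions
  pidx <- match(strat, paste(as.character(ptab$severity), ptab$age_low, ptab$sex))
  if (anyNA(pidx)) {
    miss <- unique(strat[is.na(pidx)])
    stop("split_by_tinnitus: missing tinnitus proportions for strata: ",
         paste(utils::head(miss, 5), collapse = "; "),
         if (length(miss) > 5) " ...")
  }
  D <- n_draws(surface)
  u_str <- !duplicated(pidx)
  if (!is.null(seed)) {
    local_rng(seed)
    # one t draw per proportion stratum per draw, shared across causes/cells
    upid <- unique(pidx)
    tmat_u <- matrix(stats::rnorm(length(upid) * D,
                                  ptab$proportion[upid], ptab$se[upid]),
                     length(upid), D)
    tmat_u[tmat_u < 0] <- 0
    tmat_u[tmat_u > 1] <- 1
    tmat <- tmat_u[match(pidx, upid), , drop = FALSE]
  } else {
    tmat <- matrix(ptab$proportion[pidx], nrow(k), D)
  }
  with_keys <- k
  with_keys$ringing <- TRUE
  without_keys <- k
  without_keys$ringing <- FALSE
  draw_surface(dplyr::bind_rows(with_keys, without_keys),
               rbind(surface$draws * tmat, surface$draws * (1 - tmat)))
}
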