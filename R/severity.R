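#' Severity taxonomy for bilateral hearing loss
#'
#' Hearing loss is graded on the better-ear pure-tone average (PTA) across
#' 0.5, 1, 2 and 4 kHz. The default scheme has seven mutually exclusive
#' categories: normal hearing below 20 dB, then mild, moderate, moderately
#' severe, severe, profound and complete loss. Category bounds are half-open
#' real intervals `[db_low, db_high)` so that every non-negative PTA maps to
#' exactly one category; the top category is unbounded above.
#'
#' @param categories Data frame with columns `category`, `db_low`, `db_high`
#'   (dB; `db_high = Inf` for the top category). Rows must be contiguous,
#'   non-overlapping and ordered by `db_low`, starting at 0 dB.
#' @param reference_frequencies Numeric vector of kHz values averaged into
#'   the PTA (informational).
#'
#' @return An object of class `severity_scheme`: a list with elements
#'   `categories` (tibble) and `reference_frequencies`.
#' @export
#' @examples
#' sch <- severity_scheme()
#' classify_threshold(c(5, 22, 35, 120), sch)
severity_scheme <- function(categories = default_severity_categories(),
                            reference_frequencies = c(0.5, 1, 2, 4)) {
  categories <- tibble::as_tibble(categories)
  stopifnot(all(c("category", "db_low", "db_high") %in% names(categories)))
  if (nrow(categories) < 1L) stop("severity scheme needs at least one category")
  o <- order(categories$db_low)
  categories <- categories[o, ]
  if (categories$db_low[1] != 0) stop("first severity category must start at 0 dB")
  if (any(categories$db_high <= categories$db_low)) {
    stop("each category needs db_low < db_high")
  }
  if (nrow(categories) > 1L) {
    gaps <- categories$db_low[-1] != categories$db_high[-nrow(categories)]
    if (any(gaps)) stop("severity categories must be contiguous (no gaps or overlaps)")
  }
  if (is.finite(categories$db_high[nrow(categories)])) {
    stop("top severity category must be unbounded above (db_high = Inf)")
  }
  structure(
    list(categories = categories, reference_frequencies = reference_frequencies),
    class = "severity_scheme"
  )
}

#' @rdname severity_scheme
#' @export
default_severity_categories <- function() {
  tibble::tibble(
    category = c("normal", "mild", "moderate", "moderately severe",
                 "severe", "profound", "complete"),
    db_low = c(0, 20, 35, 50, 65, 80, 95),
    db_high = c(20, 35, 50, 65, 80, 95, Inf)
  )
}

#' @export
print.severity_scheme <- function(x, ...) {
  cat("<severity_scheme> ", nrow(x$categories), " categories, PTA over ",
      paste(x$reference_frequencies, collapse = "/"), " kHz\n", sep = "")
  print(x$categories)
  invisible(x)
}

#' Ordered severity category names of a scheme
#'
#' @param scheme A [severity_scheme()].
#' @param loss_only Drop the leading "normal" category.
#' @param moderate_plus Keep only categories starting at or above 35 dB
#'   (the moderate-to-complete envelope).
#' @return Character vector of category names in increasing severity order.
#' @export
severity_levels <- function(scheme = severity_scheme(), loss_only = FALSE,
                            moderate_plus = FALSE) {
  cats <- scheme$categories
  if (moderate_plus) cats <- cats[cats$db_low >= 35, ]
  else if (loss_only) cats <- cats[cats$db_low >= 20, ]
  cats$category
}

#' Classify pure-tone averages into severity categories
#'
#' @param pta_db Numeric vector of better-ear pure-tone averages in dB.
#'   Must be finite and non-negative.
#' @param scheme A [severity_scheme()].
#' @return Factor of category names with levels in severity order.
#' @export
classify_threshold <- function(pta_db, scheme = severity_scheme()) {
  if (length(pta_db) == 0L) {
    return(factor(character(), levels = scheme$categories$category))
  }
  if (!is.numeric(pta_db) || any(!is.finite(pta_db)) || any(pta_db < 0)) {
    stop("pta_db must be finite and >= 0 dB")
  }
  brks <- c(scheme$categories$db_low, Inf)
  idx <- findInterval(pta_db, brks, left.open = FALSE)
  factor(scheme$categories$category[idx], levels = scheme$categories$category)
}

#' Disability weight table for hearing-loss health states
#'
#' Each non-normal severity category carries two health states, with and
#' without concurrent tinnitus (ringing); normal hearing carries a single
#' state with weight zero. Weights are unitless severity coefficients in
#' \[0, 1\] used to convert prevalence into years lived with disability.
#' The default table is read from a packaged delimited-text resource.
#'
#' @param path Optional path to an alternative tab-separated table with
#'   columns `state`, `severity`, `ringing`, `db_low`, `db_high`, `weight`,
#'   `lower`, `upper`.
#' @return A tibble of class `dw_table`.
#' @export
#' @examples
#' dw <- disability_weights()
#' lookup_weight("mild", dw)
#' lookup_weight(health_state("complete", ringing = TRUE), dw)
disability_weights <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "disability_weights.tsv", package = "hearburden")
  }
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tab <- tibble::as_tibble(tab)
  validate_dw_table(tab)
  class(tab) <- c("dw_table", class(tab))
  tab
}

validate_dw_table <- function(tab) {
  need <- c("state", "severity", "ringing", "weight", "lower", "upper")
  stopifnot(all(need %in% names(tab)))
  if (any(tab$weight < 0 | tab$weight > 1)) stop("disability weights must lie in [0, 1]")
  if (any(tab$lower > tab$weight | tab$weight > tab$upper)) {
    stop("each weight must satisfy lower <= weight <= upper")
  }
  if (any(tab$ringing & tab$severity == "normal")) {
    stop("normal hearing admits no ringing health state")
  }
  ring <- tab[tab$severity != "normal", ]
  byser <- split(ring, ring$severity)
  for (b in byser) {
    if (nrow(b) != 2L || sum(b$ringing) != 1L) {
      stop("each non-normal severity needs exactly one ringing and one non-ringing state")
    }
    if (b$weight[b$ringing] < b$weight[!b$ringing]) {
      stop("ringing weight must be >= non-ringing weight within a severity")
    }
  }
  invisible(tab)
}

#' Construct a health-state identifier
#'
#' @param severity Severity category name (e.g. `"moderate"`).
#' @param ringing Logical; tinnitus present. Must be `FALSE` for `"normal"`.
#' @return The canonical state id string used in [disability_weights()].
#' @export
health_state <- function(severity, ringing = FALSE) {
  if (any(ringing & severity == "normal")) {
    stop("normal hearing has no ringing variant")
  }
  base <- gsub(" ", "_", severity)
  ifelse(ringing, paste0(base, "_ringing"), base)
}

#' Look up the point disability weight of a health state
#'
#' @param state A state id (from [health_state()]) or vector thereof.
#' @param table A [disability_weights()] table.
#' @return Numeric vector of point weights.
#' @export
lookup_weight <- function(state, table = disability_weights()) {
  idx <- match(state, table$state)
  if (anyNA(idx)) {
    stop("unknown health state(s): ", paste(state[is.na(idx)], collapse = ", "))
  }
  table$weight[idx]
}
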