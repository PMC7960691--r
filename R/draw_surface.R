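#' Draw surfaces: prevalence estimates stored as posterior draws
#'
#' A `draw_surface` couples a key table (one row per estimation cell, e.g.
#' location x year x sex x age group x category) with a numeric matrix of
#' posterior draws, one row per cell and one column per draw. All burden
#' arithmetic in the package — squeezes, hearing-aid shifts, cause and
#' tinnitus splits, YLD computation, aggregation — operates cell-wise on the
#' draw matrix so that uncertainty propagates through every step and
#' intervals are read off the final draws.
#'
#' @param keys Data frame of cell identifiers; must not contain a column
#'   named `draws` and must have unique rows.
#' @param draws Numeric matrix with `nrow(keys)` rows; or a vector recycled
#'   to a one-column matrix.
#' @return An object of class `draw_surface`.
#' @export
draw_surface <- function(keys, draws) {
  keys <- tibble::as_tibble(keys)
  if (!is.matrix(draws)) draws <- matrix(draws, nrow = nrow(keys))
  if (nrow(draws) != nrow(keys)) stop("draws must have one row per key row")
  if (!is.numeric(draws)) stop("draws must be numeric")
  dimnames(draws) <- NULL
  structure(list(keys = keys, draws = draws), class = "draw_surface")
}

#' @export
print.draw_surface <- function(x, ...) {
  cat("<draw_surface> ", nrow(x$keys), " cells x ", ncol(x$draws), " draws; keys: ",
      paste(names(x$keys), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname draw_surface
#' @param x A `draw_surface`.
#' @export
n_draws <- function(x) ncol(x$draws)

#' Align one draw surface to the cell order of another
#'
#' Reorders `x` so its key rows match `template` row by row on the shared
#' key columns. Errors if any template cell is missing from `x`.
#'
#' @param x,template `draw_surface` objects (or a key tibble for `template`).
#' @param by Key columns to match on; default all columns of the template keys
#'   that also exist in `x`.
#' @return `x` with rows reordered to the template.
#' @export
ds_align <- function(x, template, by = NULL) {
  tkeys <- if (inherits(template, "draw_surface")) template$keys else tibble::as_tibble(template)
  if (is.null(by)) by <- intersect(names(tkeys), names(x$keys))
  if (length(by) == 0L) stop("no shared key columns to align on")
  idx <- vctrs_match(tkeys[by], x$keys[by])
  if (anyNA(idx)) stop("ds_align: ", sum(is.na(idx)), " template cells missing from surface")
  draw_surface(x$keys[idx, , drop = FALSE], x$draws[idx, , drop = FALSE])
}

# row-wise match of two key data frames (base implementation; avoids a
# dependency for what is a single interaction-key lookup)
vctrs_match <- function(needle, haystack) {
  key <- function(df) do.call(paste, c(lapply(df, as.character), sep = "\r"))
  match(key(needle), key(haystack))
}

#' Summarise draws into mean and 95% uncertainty interval
#'
#' The interval convention follows draw-based burden reporting: with
#' D = 1000 draws the bounds are exactly the 25th and 975th order
#' statistics; for other draw counts the nearest-rank empirical 2.5th and
#' 97.5th percentiles (`sort(x)[ceiling(0.025 * D)]` and
#' `sort(x)[ceiling(0.975 * D)]`), which reproduces the 1000-draw rule.
#'
#' @param draws Numeric vector (one cell's draws) or a matrix (cells x draws).
#' @return For a vector, a named numeric `c(mean, lower, upper)`; for a
#'   matrix, a tibble with columns `mean`, `lower`, `upper` (one row per cell).
#' @export
#' @examples
#' summarize_draws(1:1000)  # lower 25, upper 975
summarize_draws <- function(draws) {
  if (is.matrix(draws)) {
    d <- ncol(draws)
    if (d < 2L) stop("need at least 2 draws to summarise")
    lo <- ceiling(0.025 * d)
    hi <- ceiling(0.975 * d)
    srt <- apply(draws, 1L, sort)  # draws x cells
    return(tibble::tibble(
      mean = rowMeans(draws),
      lower = srt[lo, ],
      upper = srt[hi, ]
    ))
  }
  if (length(draws) < 2L) stop("need at least 2 draws to summarise")
  s <- sort(draws)
  d <- length(draws)
  c(mean = mean(draws), lower = s[ceiling(0.025 * d)], upper = s[ceiling(0.975 * d)])
}

#' Attach draw summaries to the key table of a surface
#'
#' @param x A `draw_surface`.
#' @return The key tibble with `mean`, `lower`, `upper` columns appended.
#' @export
ds_summary <- function(x) {
  dplyr::bind_cols(x$keys, summarize_draws(x$draws))
}

#' Filter the cells of a draw surface
#'
#' @param x A `draw_surface`.
#' @param ... Logical conditions evaluated in the key table.
#' @return A `draw_surface` restricted to matching cells.
#' @export
ds_filter <- function(x, ...) {
  conds <- rlang::quos(...)
  keep <- rep(TRUE, nrow(x$keys))
  for (q in conds) keep <- keep & rlang::eval_tidy(q, data = x$keys)
  draw_surface(x$keys[keep, , drop = FALSE], x$draws[keep, , drop = FALSE])
}

#' Sum draw surfaces over grouping columns
#'
#' Draws are added at draw level within groups, so downstream intervals are
#' computed on sums of draws rather than sums of interval bounds.
#'
#' @param x A `draw_surface`.
#' @param by Character vector of key columns to retain (groups).
#' @return A `draw_surface` keyed by `by`.
#' @export
ds_sum_over <- function(x, by) {
  stopifnot(all(by %in% names(x$keys)))
  if (length(by) == 0L) {
    return(draw_surface(tibble::new_tibble(list(), nrow = 1L),
                        matrix(colSums(x$draws), 1L)))
  }
  g <- do.call(paste, c(lapply(x$keys[by], as.character), sep = "\r"))
  gi <- match(g, unique(g))
  out_keys <- x$keys[!duplicated(gi), by, drop = FALSE]
  out <- rowsum(x$draws, gi, reorder = FALSE)
  dimnames(out) <- NULL
  draw_surface(out_keys, out)
}

#' Write / read a draw surface as a delimited long-format table
#'
#' One row per (cell, draw index); plain text for audit and interchange.
#'
#' @param x A `draw_surface`.
#' @param path File path.
#' @export
write_draw_surface <- function(x, path) {
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(x$keys, as.data.frame(x$draws) |>
                       stats::setNames(paste0("draw_", seq_len(ncol(x$draws))))),
    dplyr::starts_with("draw_"), names_to = "draw", values_to = "value"
  )
  long$draw <- as.integer(sub("draw_", "", long$draw))
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_draw_surface
#' @export
read_draw_surface <- function(path) {
  long <- tibble::as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  keycols <- setdiff(names(long), c("draw", "value"))
  wide <- tidyr::pivot_wider(long, names_from = "draw", values_from = "value",
                             names_prefix = "draw_")
  draws <- as.matrix(wide[grep("^draw_", names(wide))])
  draw_surface(wide[keycols], draws)
}
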