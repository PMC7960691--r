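# Shared desk-scale fixtures, built once per test run.

tiny_truth_config <- function(...) {
  truth_config(n_regions = 2L, locations_per_region = 2L,
               years = c(2010L, 2019L), ...)
}

# one small world + survey reused across module tests
tiny_truth <- make_truth(tiny_truth_config(), seed = 42L)
tiny_micro <- simulate_microdata(tiny_truth, n_per_stratum = 2000L, seed = 43L)

# a draw surface with arbitrary values on a small grid
random_surface <- function(n_cells = 50L, n_draws = 20L, seed = 1L,
                           max_value = 1) {
  set.seed(seed)
  keys <- tibble::tibble(location = sprintf("L%02d", seq_len(n_cells)),
                         year = 2019L, sex = "female", age_low = 0L)
  draw_surface(keys, matrix(stats::runif(n_cells * n_draws, 0, max_value),
                            n_cells, n_draws))
}

# single-cell category surface builder for shift/split arithmetic tests
one_cell_surface <- function(values, n_draws = 4L) {
  cats <- names(values)
  keys <- tibble::tibble(location = "A", year = 2019L, sex = "female",
                         age_low = 40L,
                         category = factor(cats, levels = cats))
  draw_surface(keys, matrix(rep(unname(values), n_draws), length(values), n_draws))
}
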