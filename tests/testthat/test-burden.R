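# YLD computation, aggregation, age standardisation, change measures.

state_cell <- function(category, ringing, p, pop = 1000, n_draws = 3L) {
  keys <- tibble::tibble(location = "A", year = 2019L, sex = "female",
                         age_low = 40L, category = category, ringing = ringing)
  list(surface = draw_surface(keys, matrix(p, 1, n_draws)),
       population = tibble::tibble(location = "A", year = 2019L,
                                   sex = "female", age_low = 40L, pop = pop))
}

test_that("unit prevalence yields the disability weight as the YLD rate", {
  dw <- disability_weights()
  for (i in seq_len(nrow(dw))) {
    if (dw$severity[i] == "normal") next
    sc <- state_cell(dw$severity[i], dw$ringing[i], 1)
    b <- compute_ylds(sc$surface, dw, sc$population, dw_uncertainty = FALSE)
    expect_equal(b$yld_rate[1, 1], dw$weight[i], tolerance = 1e-12)
    expect_equal(b$ylds[1, 1], dw$weight[i] * 1000, tolerance = 1e-9)
  }
})

test_that("YLDs combine linearly across states", {
  dw <- disability_weights()
  keys <- tibble::tibble(location = "A", year = 2019L, sex = "female",
                         age_low = 40L,
                         category = c("moderate", "moderate"),
                         ringing = c(FALSE, TRUE))
  pop <- tibble::tibble(location = "A", year = 2019L, sex = "female",
                        age_low = 40L, pop = 500)
  s <- draw_surface(keys, matrix(0.1, 2, 4))
  b <- compute_ylds(s, dw, pop, dw_uncertainty = FALSE)
  expect_equal(sum(b$yld_rate[, 1]), 0.1 * 0.027 + 0.1 * 0.074,
               tolerance = 1e-12)
  s2 <- draw_surface(keys, matrix(0.2, 2, 4))
  b2 <- compute_ylds(s2, dw, pop, dw_uncertainty = FALSE)
  expect_equal(b2$ylds, 2 * b$ylds, tolerance = 1e-12)
})

test_that("disability-weight uncertainty widens but centres the YLD draws", {
  sc <- state_cell("severe", TRUE, 0.5, n_draws = 2000L)
  fixed <- compute_ylds(sc$surface, population = sc$population,
                        dw_uncertainty = FALSE)
  drawn <- compute_ylds(sc$surface, population = sc$population,
                        dw_uncertainty = TRUE, seed = 3L)
  expect_equal(stats::sd(fixed$yld_rate[1, ]), 0)
  expect_gt(stats::sd(drawn$yld_rate[1, ]), 0)
  # logit-normal resampling stays within the published interval most of the time
  dw <- disability_weights()
  lo <- 0.5 * dw$lower[dw$state == "severe_ringing"]
  hi <- 0.5 * dw$upper[dw$state == "severe_ringing"]
  inside <- mean(drawn$yld_rate[1, ] >= lo & drawn$yld_rate[1, ] <= hi)
  expect_gt(inside, 0.9)
  # and resampling is deterministic in the seed
  again <- compute_ylds(sc$surface, population = sc$population,
                        dw_uncertainty = TRUE, seed = 3L)
  expect_identical(drawn$yld_rate, again$yld_rate)
})

test_that("normal hearing contributes zero YLDs even with dw uncertainty", {
  sc <- state_cell("normal", FALSE, 1, n_draws = 100L)
  b <- compute_ylds(sc$surface, population = sc$population,
                    dw_uncertainty = TRUE, seed = 1L)
  expect_true(all(b$yld_rate == 0))
})

test_that("aggregation sums counts at draw level over the hierarchy", {
  keys <- tibble::tibble(location = c("A", "B"), year = 2019L)
  bt <- structure(list(keys = keys,
                       cases = matrix(c(3, 4, 30, 40), 2, 2),
                       ylds = matrix(c(1, 2, 10, 20), 2, 2)),
                  class = "burden_table")
  h <- tibble::tibble(location = c("A", "B"), region = c("R1", "R2"))
  agg <- aggregate_burden(bt, h, by = "year")
  expect_equal(agg$cases[agg$keys$region == "R1", ], c(3, 30))
  expect_equal(agg$cases[agg$keys$region == "R2", ], c(4, 40))
  expect_equal(agg$cases[agg$keys$region == "global", ], c(7, 70))
  expect_equal(agg$ylds[agg$keys$region == "global", ], c(3, 30))
  # one-region hierarchy: the region equals the global row
  h1 <- tibble::tibble(location = c("A", "B"), region = "R1")
  agg1 <- aggregate_burden(bt, h1, by = "year")
  expect_equal(agg1$cases[agg1$keys$region == "R1", ],
               agg1$cases[agg1$keys$region == "global", ])
  expect_error(aggregate_burden(bt, h[1, ], by = "year"), "unmapped")
})

test_that("age standardisation applies fixed weights at draw level", {
  keys <- tibble::tibble(location = "A", age_low = c(0L, 5L))
  std <- tibble::tibble(age_low = c(0L, 5L), weight = c(0.5, 0.5))
  s <- draw_surface(keys, matrix(c(0.1, 0.3, 0.2, 0.6), 2, 2))
  asr <- age_standardize(s, std)
  expect_equal(asr$draws, matrix(c(0.2, 0.4), 1, 2), tolerance = 1e-12)
  # a constant rate is its own standardised rate
  sc <- draw_surface(keys, matrix(0.25, 2, 3))
  expect_true(all(abs(age_standardize(sc, std)$draws - 0.25) < 1e-12))
  # unequal weights
  std2 <- tibble::tibble(age_low = c(0L, 5L), weight = c(0.9, 0.1))
  expect_equal(age_standardize(s, std2)$draws[1, 1], 0.9 * 0.1 + 0.1 * 0.3,
               tolerance = 1e-12)
})

test_that("age standardisation demands full coverage of the standard", {
  std <- tibble::tibble(age_low = c(0L, 5L), weight = c(0.5, 0.5))
  s <- draw_surface(tibble::tibble(location = "A", age_low = 0L),
                    matrix(0.1, 1, 2))
  expect_error(age_standardize(s, std), "missing age groups")
  s2 <- draw_surface(tibble::tibble(location = "A", age_low = c(0L, 10L)),
                     matrix(0.1, 2, 2))
  expect_error(age_standardize(s2, std), "no standard weight")
  bad_std <- tibble::tibble(age_low = 0L, weight = 0.7)
  expect_error(age_standardize(s, bad_std))
})

test_that("percent change follows the draw-level definition", {
  expect_equal(unname(percent_change(rep(2, 10), rep(2, 10))["mean"]), 0)
  pc <- percent_change(rep(1.57, 10), rep(2.45, 10))
  expect_equal(round(unname(pc["mean"]), 1), 56.1)
  expect_equal(round(unname(pc["point"]), 1), 56.1)
  expect_error(percent_change(c(0, 1), c(1, 2)), "must be positive")
  # draw-level mean change vs change of means can differ; both are exposed
  a <- c(1, 4)
  b <- c(2, 4)
  pc2 <- percent_change(a, b)
  expect_equal(unname(pc2["mean"]), 50)
  expect_equal(unname(pc2["point"]), 100 * (3 - 2.5) / 2.5)
})

test_that("the HAQ regression explains a perfect linear relation", {
  d <- tibble::tibble(haq = seq(40, 90, length.out = 12),
                      asr_yld = 900 - 5 * seq(40, 90, length.out = 12))
  h <- suppressWarnings(haq_regression(d))  # exact fit: lm warns harmlessly
  expect_equal(h$adj_r2, 1, tolerance = 1e-9)
  expect_equal(h$slope, -5, tolerance = 1e-9)
  set.seed(9)
  d2 <- d
  d2$asr_yld <- sample(d$asr_yld)
  h2 <- haq_regression(d2)
  expect_lt(h2$adj_r2, 0.5)
  expect_error(haq_regression(d[1:2, ]), "at least 3")
  d3 <- d
  d3$haq <- 50
  expect_error(haq_regression(d3), "constant")
})

test_that("the severity report table is internally additive", {
  set.seed(27)
  cats <- severity_levels()
  keys <- tidyr::crossing(location = c("A", "B", "C", "D"), year = 2019L,
                          sex = "female", age_low = c(0L, 5L),
                          category = factor(cats, levels = cats))
  n <- nrow(keys)
  draws <- matrix(runif(n * 4), n, 4)
  cell <- paste(keys$location, keys$age_low)
  for (d in 1:4) draws[, d] <- draws[, d] / ave(draws[, d], cell, FUN = sum)
  surf <- draw_surface(keys, draws)
  pop <- tidyr::crossing(location = c("A", "B", "C", "D"), year = 2019L,
                         sex = "female", age_low = c(0L, 5L))
  pop$pop <- c(1000, 2000, 1500, 800, 1200, 900, 700, 600)
  h <- tibble::tibble(location = c("A", "B", "C", "D"),
                      region = c("R1", "R1", "R2", "R2"))
  std <- tibble::tibble(age_low = c(0L, 5L), weight = c(0.6, 0.4))
  rep_tab <- report_severity_table(surf, pop, h, std, year = 2019L)

  get <- function(cat, reg, col) rep_tab[[col]][rep_tab$category == cat &
                                                  rep_tab$region == reg]
  for (reg in c("R1", "R2", "global")) {
    expect_equal(get("all_loss", reg, "cases_mean"),
                 get("mild", reg, "cases_mean") +
                   get("mod_plus", reg, "cases_mean"), tolerance = 1e-9)
    sev5 <- setdiff(cats, c("normal", "mild"))
    expect_equal(get("mod_plus", reg, "cases_mean"),
                 sum(sapply(sev5, get, reg = reg, col = "cases_mean")),
                 tolerance = 1e-9)
    expect_equal(get("all_loss", reg, "asr_mean"),
                 get("mild", reg, "asr_mean") + get("mod_plus", reg, "asr_mean"),
                 tolerance = 1e-9)
  }
  expect_equal(get("all_loss", "global", "cases_mean"),
               get("all_loss", "R1", "cases_mean") +
                 get("all_loss", "R2", "cases_mean"), tolerance = 1e-9)
  expect_equal(rep_tab$cases_millions,
               round(rep_tab$cases_mean / 1e6, 1))
})
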