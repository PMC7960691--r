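# Harmonisation: sex-ratio meta-regression, sex split, crosswalk, age split.

make_pairs <- function(pf, pm, n = 2000, ages = 50L) {
  k <- length(pf)
  base <- tibble::tibble(
    location = sprintf("S%03d", seq_len(k)), year = 2019L,
    age_low = rep_len(ages, k), age_high = rep_len(ages, k) + 5L,
    db_low = 35, db_high = Inf
  )
  dplyr::bind_rows(
    dplyr::mutate(base, sex = "female", prevalence = pf,
                  effective_sample_size = n),
    dplyr::mutate(base, sex = "male", prevalence = pm,
                  effective_sample_size = n)
  )
}

test_that("identical sex-specific prevalences give a zero log ratio", {
  d <- make_pairs(rep(0.12, 10), rep(0.12, 10))
  m <- fit_sex_ratio(d, trim = 0)
  expect_equal(m$pooled$log_ratio, 0, tolerance = 1e-12)
})

test_that("a constant female/male ratio is recovered", {
  set.seed(31)
  n <- 2000
  xm <- rbinom(60, n, 0.10)
  xf <- rbinom(60, n, 0.15)
  d <- make_pairs(pmax(xf, 1) / n, pmax(xm, 1) / n, n = n)
  m <- fit_sex_ratio(d, trim = 0.10)
  expect_lt(abs(m$pooled$log_ratio - log(1.5)), 2 * m$pooled$se + 0.02)
})

test_that("trimming removes the most outlying pair", {
  pf <- c(rep(0.10, 10), 0.40)
  pm <- rep(0.10, 11)
  m <- fit_sex_ratio(make_pairs(pf, pm), trim = 0.10)
  expect_equal(m$pooled$log_ratio, 0, tolerance = 1e-12)
  m0 <- fit_sex_ratio(make_pairs(pf, pm), trim = 0)
  expect_gt(m0$pooled$log_ratio, 0.01)
})

test_that("per-age estimates are used with a pooled fallback", {
  d <- dplyr::bind_rows(make_pairs(rep(0.2, 5), rep(0.1, 5), ages = 40L),
                        make_pairs(rep(0.1, 5), rep(0.2, 5), ages = 60L))
  m <- fit_sex_ratio(d, trim = 0)
  e40 <- hearburden:::sex_ratio_lookup(m, 40L)
  e60 <- hearburden:::sex_ratio_lookup(m, 60L)
  expect_gt(e40$log_ratio, 0)
  expect_lt(e60$log_ratio, 0)
  # unseen age group falls back to the pooled estimate
  ep <- hearburden:::sex_ratio_lookup(m, 85L)
  expect_equal(ep$log_ratio, m$pooled$log_ratio)
})

ratio_model <- function(ratio, se = 0, tau2 = 0) {
  structure(list(estimates = NULL,
                 pooled = tibble::tibble(log_ratio = log(ratio), se = se,
                                         tau2 = tau2, age_low = NA_integer_),
                 trim = 0.1),
            class = "sex_ratio_model")
}

both_row <- function(p = 0.15, n = 1000, age_low = 50L, age_high = 55L) {
  tibble::tibble(location = "A", region = "R", year = 2019L, sex = "both",
                 age_low = age_low, age_high = age_high, db_low = 35,
                 db_high = Inf, prevalence = p, effective_sample_size = n,
                 definition = "reference")
}

pop_equal <- function(ages = seq(0L, 95L, 5L), pop = 1000) {
  tidyr::crossing(location = "A", year = 2019L, sex = c("female", "male"),
                  age_low = ages) |>
    dplyr::mutate(pop = pop)
}

test_that("sex split solves the ratio and conservation equations", {
  out <- apply_sex_split(both_row(0.15), ratio_model(2), pop_equal())
  pf <- out$prevalence[out$sex == "female"]
  pm <- out$prevalence[out$sex == "male"]
  expect_equal(pf, 0.20, tolerance = 1e-12)
  expect_equal(pm, 0.10, tolerance = 1e-12)
  expect_equal(pf / pm, 2, tolerance = 1e-12)
})

test_that("sex split conserves expected cases under unequal populations", {
  pop <- pop_equal()
  pop$pop[pop$sex == "female"] <- 3000
  out <- apply_sex_split(both_row(0.08), ratio_model(1.7), pop)
  pf <- out$prevalence[out$sex == "female"]
  pm <- out$prevalence[out$sex == "male"]
  expect_equal((3000 * pf + 1000 * pm) / 4000, 0.08, tolerance = 1e-9)
  expect_equal(pf / pm, 1.7, tolerance = 1e-9)
})

test_that("sex split deflates the effective sample size under ratio uncertainty", {
  exact <- apply_sex_split(both_row(), ratio_model(2, se = 0), pop_equal())
  noisy <- apply_sex_split(both_row(), ratio_model(2, se = 0.3), pop_equal())
  expect_true(all(noisy$effective_sample_size < exact$effective_sample_size))
  expect_equal(sum(exact$effective_sample_size), 1000, tolerance = 1e-9)
})

test_that("a unit ratio splits into two equal halves", {
  out <- apply_sex_split(both_row(0.3), ratio_model(1), pop_equal())
  expect_equal(out$prevalence, c(0.3, 0.3))
})

test_that("crosswalk of a range onto itself is the identity", {
  cw <- fit_crosswalk(tiny_micro, alternative_ranges = list(c(35, Inf)),
                      reference_ranges = list(c(35, Inf)))
  expect_equal(cw$coefficient, 0, tolerance = 1e-12)
  expect_equal(cw$se, 0, tolerance = 1e-12)
})

test_that("a broader alternative range has a positive coefficient", {
  cw <- fit_crosswalk(tiny_micro, alternative_ranges = list(c(30, Inf)))
  expect_gt(cw$coefficient, 0)
  expect_gt(cw$n_cells, 0)
})

test_that("crosswalk adjustment matches the analytic logit shift", {
  cw <- tibble::tibble(alt_low = 30, alt_high = Inf, ref_low = 35,
                       ref_high = Inf, coefficient = 0.4, se = 0,
                       n_cells = 10L, n_excluded = 0L)
  class(cw) <- c("crosswalk_model", class(cw))
  d <- both_row(0.5)
  d$sex <- "female"
  d$db_low <- 30
  d$definition <- "alternative"
  out <- apply_crosswalk(d, cw)
  expect_equal(out$prevalence, plogis(qlogis(0.5) - 0.4), tolerance = 1e-12)
  expect_equal(out$db_low, 35)
  expect_equal(out$definition, "reference")
})

test_that("crosswalk applies half-case continuity at the boundaries", {
  cw <- tibble::tibble(alt_low = 30, alt_high = Inf, ref_low = 35,
                       ref_high = Inf, coefficient = 0.2, se = 0,
                       n_cells = 10L, n_excluded = 0L)
  class(cw) <- c("crosswalk_model", class(cw))
  d <- both_row(0)
  d$db_low <- 30
  out <- apply_crosswalk(d, cw)
  expect_equal(out$prevalence,
               plogis(qlogis(0.5 / 1001) - 0.2), tolerance = 1e-12)
  expect_error(apply_crosswalk(dplyr::mutate(both_row(), db_low = 25), cw),
               "no coefficient")
})

test_that("crosswalk adjustment approximately recovers reference tabulations", {
  alt <- tabulate_survey(tiny_micro, db_ranges = list(c(30, Inf)))
  ref <- tabulate_survey(tiny_micro, db_ranges = list(c(35, Inf)))
  cw <- fit_crosswalk(tiny_micro, alternative_ranges = list(c(30, Inf)))
  adj <- apply_crosswalk(alt, cw)
  j <- dplyr::inner_join(adj, ref, by = c("location", "year", "sex", "age_low"),
                         suffix = c("_adj", "_ref"))
  # a single mean shift cannot match every cell, but the aggregate bias is
  # removed: the mean residual on the logit scale is near zero
  ok <- j$prevalence_adj > 0 & j$prevalence_adj < 1 &
    j$prevalence_ref > 0 & j$prevalence_ref < 1
  resid <- qlogis(j$prevalence_adj[ok]) - qlogis(j$prevalence_ref[ok])
  expect_lt(abs(mean(resid)), 0.1)
})

flat_pattern <- function(ages = seq(0L, 95L, 5L)) {
  tibble::tibble(age_low = ages, rel_prev = 1)
}

test_that("age split with a flat pattern returns the input prevalence", {
  d <- both_row(0.10, age_low = 0L, age_high = 100L)
  d$sex <- "female"
  out <- age_split(d, flat_pattern(), pop_equal())
  expect_equal(nrow(out), 20L)
  expect_equal(out$prevalence, rep(0.10, 20))
  expect_equal(out$age_low, seq(0L, 95L, 5L))
  expect_equal(out$age_high, seq(5L, 100L, 5L))
})

test_that("age split follows the pattern and conserves expected cases", {
  pat <- tibble::tibble(age_low = c(0L, 5L), rel_prev = c(1, 2))
  d <- both_row(0.15, age_low = 0L, age_high = 10L)
  d$sex <- "male"
  out <- age_split(d, pat, pop_equal(), max_span = 5)
  expect_equal(out$prevalence, c(0.10, 0.20), tolerance = 1e-12)
  # conservation with unequal populations
  pop <- pop_equal()
  pop$pop[pop$age_low == 0] <- 4000
  out2 <- age_split(d, pat, pop, max_span = 5)
  w <- c(4000, 1000) / 5000
  expect_equal(sum(w * out2$prevalence), 0.15, tolerance = 1e-12)
})

test_that("short spans pass through untouched and errors are explicit", {
  d <- both_row(0.2, age_low = 50L, age_high = 55L)
  expect_identical(age_split(d, flat_pattern(), pop_equal()), d)
  wide <- both_row(0.2, age_low = 0L, age_high = 50L)
  expect_error(age_split(wide, tibble::tibble(age_low = 0L, rel_prev = 1),
                         pop_equal()), "pattern missing")
})

test_that("harmonisation is idempotent on already-reference data", {
  ref <- tabulate_survey(tiny_micro, db_ranges = list(c(35, Inf)))
  out <- process_survey_data(ref, age_pattern = flat_pattern(),
                             population = tiny_truth$population)
  expect_equal(as.data.frame(out), as.data.frame(ref), ignore_attr = TRUE)
})

test_that("mixed-definition tables are fully harmonised", {
  ref <- tabulate_survey(tiny_micro, db_ranges = list(c(35, Inf)))
  both <- tabulate_survey(tiny_micro, db_ranges = list(c(30, Inf)),
                          pool_sexes = TRUE)
  cw <- fit_crosswalk(tiny_micro, alternative_ranges = list(c(30, Inf)))
  sx <- fit_sex_ratio(ref, trim = 0)
  out <- process_survey_data(dplyr::bind_rows(ref, both), sex_model = sx,
                             crosswalk = cw,
                             age_pattern = tiny_truth$age_pattern,
                             population = tiny_truth$population)
  expect_true(all(out$definition == "reference"))
  expect_true(all(out$sex %in% c("female", "male")))
  expect_true(all(out$age_high - out$age_low <= 20))
  expect_error(process_survey_data(both, sex_model = NULL, crosswalk = cw,
                                   age_pattern = tiny_truth$age_pattern,
                                   population = tiny_truth$population),
               "no sex-ratio model")
})
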