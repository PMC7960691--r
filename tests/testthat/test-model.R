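# Prevalence surface models and the two-stage squeeze.

# survey-like rows with binomial sampling noise around a true field; exact
# noise-free fields make the quasibinomial fit degenerate (zero deviance),
# which the surrogate is not designed for
flat_band_data <- function(p = 0.3, ess = 1000,
                           locations = sprintf("L%02d", 1:4),
                           ages = seq(0L, 95L, 5L), seed = 100L) {
  set.seed(seed)
  d <- tidyr::crossing(location = locations, year = 2019L,
                       sex = c("female", "male"), age_low = ages)
  d$prevalence <- rbinom(nrow(d), ess, p) / ess
  d$effective_sample_size <- ess
  d
}

test_that("a constant prevalence field is recovered", {
  d <- flat_band_data(0.3)
  fit <- fit_category_model(d, model_config(covariates = NULL, n_draws = 100,
                                            seed = 2L))
  s <- ds_summary(fit)
  expect_equal(nrow(s), nrow(d))
  expect_true(all(abs(s$mean - 0.3) < 0.01))
})

test_that("model draws are deterministic given the config seed", {
  d <- flat_band_data(0.2, locations = sprintf("L%02d", 1:3))
  cfg <- model_config(covariates = NULL, n_draws = 20, seed = 9L)
  f1 <- fit_category_model(d, cfg)
  f2 <- fit_category_model(d, cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_category_model(d, model_config(covariates = NULL, n_draws = 20,
                                           seed = 10L))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("an age gradient in the data is reproduced by the surface", {
  set.seed(101)
  d <- flat_band_data(locations = sprintf("L%02d", 1:4))
  n <- 5000
  d$prevalence <- rbinom(nrow(d), n, plogis(-4 + 0.05 * (d$age_low + 2.5))) / n
  d$effective_sample_size <- n
  fit <- fit_category_model(d, model_config(covariates = NULL, n_draws = 50,
                                            seed = 3L))
  s <- ds_summary(fit)
  one <- s[s$location == "L01" & s$sex == "female", ]
  one <- one[order(one$age_low), ]
  expect_true(all(diff(one$mean) > 0))
  expect_true(max(abs(one$mean - plogis(-4 + 0.05 * (one$age_low + 2.5)))) < 0.02)
})

test_that("a missing sex in the data is a hard error", {
  d <- flat_band_data()
  d <- d[d$sex == "female", ]
  grid <- tidyr::crossing(location = "L01", year = 2019L,
                          sex = c("female", "male"), age_low = c(0L, 50L))
  expect_error(fit_category_model(d, model_config(covariates = NULL,
                                                  n_draws = 10), grid = grid),
               "no data for sex: male")
})

test_that("a sign-constrained covariate is dropped when violated", {
  # prevalence rises steeply with sdi, but the constraint demands sdi <= 0:
  # the covariate must be removed rather than fitted with the wrong sign
  d <- flat_band_data(locations = sprintf("L%02d", 1:6))
  covs <- tibble::tibble(location = sprintf("L%02d", 1:6), year = 2019L,
                         sdi = seq(0.2, 0.9, length.out = 6))
  d <- dplyr::left_join(d, covs, by = c("location", "year"))
  set.seed(102)
  d$prevalence <- rbinom(nrow(d), 2000, plogis(-2 + 3 * d$sdi)) / 2000
  d$effective_sample_size <- 2000
  d$sdi <- NULL
  fit <- fit_category_model(
    d, model_config(covariates = "sdi", covariate_sign = c(sdi = -1),
                    random_effect = NULL, n_draws = 10, seed = 4L),
    covariates = covs)
  expect_s3_class(fit, "draw_surface")
  # without the covariate the surface cannot track sdi: predictions for the
  # low- and high-sdi locations are pulled together relative to the truth
  s <- ds_summary(fit)
  spread_fit <- diff(range(tapply(s$mean, s$location, mean)))
  spread_truth <- diff(range(plogis(-2 + 3 * covs$sdi)))
  expect_lt(spread_fit, 0.5 * spread_truth)
})

cell_keys <- tibble::tibble(location = "A", year = 2019L, sex = "female",
                            age_low = 40L)

const_surface <- function(v, n_draws = 3L) {
  draw_surface(cell_keys, matrix(v, 1, n_draws))
}

test_that("top-level squeeze rescales to the three-way sum", {
  sq <- squeeze_top_level(const_surface(0.5), const_surface(0.4),
                          const_surface(0.3))
  expect_equal(sq$normal$draws[1, 1], 0.5 / 1.2, tolerance = 1e-12)
  expect_equal(sq$mild$draws[1, 1], 0.4 / 1.2, tolerance = 1e-12)
  expect_equal(sq$mod_plus$draws[1, 1], 0.3 / 1.2, tolerance = 1e-12)
})

test_that("top-level squeeze is the identity on already-normalised surfaces", {
  sq <- squeeze_top_level(const_surface(0.6), const_surface(0.3),
                          const_surface(0.1))
  expect_equal(sq$normal$draws[1, 1], 0.6, tolerance = 1e-12)
  expect_equal(sq$mild$draws[1, 1], 0.3, tolerance = 1e-12)
})

test_that("squeezed top-level surfaces always sum to one", {
  a <- random_surface(30, 10, seed = 2)
  b <- random_surface(30, 10, seed = 3)
  c <- random_surface(30, 10, seed = 4)
  sq <- squeeze_top_level(a, b, c)
  tot <- sq$normal$draws + sq$mild$draws + sq$mod_plus$draws
  expect_true(all(abs(tot - 1) < 1e-12))
})

test_that("severity squeeze scales the five categories to the envelope", {
  five <- lapply(1:5, function(i) const_surface(0.02))
  names(five) <- severity_levels(moderate_plus = TRUE)
  out <- squeeze_severities(five, const_surface(0.05))
  for (s in out) expect_equal(s$draws[1, 1], 0.01, tolerance = 1e-12)
  # zero envelope forces zero severities
  out0 <- squeeze_severities(five, const_surface(0))
  for (s in out0) expect_equal(s$draws[1, 1], 0)
})

test_that("squeezed severities sum exactly to the envelope everywhere", {
  five <- lapply(2:6, function(i) random_surface(20, 8, seed = i))
  names(five) <- severity_levels(moderate_plus = TRUE)
  env <- random_surface(20, 8, seed = 11, max_value = 0.5)
  out <- squeeze_severities(five, env)
  tot <- Reduce(`+`, lapply(out, function(s) s$draws))
  expect_true(all(abs(tot - env$draws) < 1e-9))
})

test_that("a positive envelope over all-zero sub-models warns and uses mean shares", {
  five <- lapply(1:5, function(i) const_surface(c(0, 0.02, 0.02), 3L))
  names(five) <- severity_levels(moderate_plus = TRUE)
  expect_warning(out <- squeeze_severities(five, const_surface(0.05, 3L)),
                 "all sub-models zero")
  tot <- Reduce(`+`, lapply(out, function(s) s$draws))
  expect_equal(as.vector(tot), rep(0.05, 3), tolerance = 1e-12)
})

test_that("stacking preserves category order and draw values", {
  parts <- list(normal = const_surface(0.7), mild = const_surface(0.2),
                moderate = const_surface(0.1))
  st <- stack_categories(parts)
  expect_equal(levels(st$keys$category), c("normal", "mild", "moderate"))
  expect_equal(st$draws[, 1], c(0.7, 0.2, 0.1))
})
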