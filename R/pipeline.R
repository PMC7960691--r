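#' Configuration of an end-to-end pipeline run
#'
#' Collects every tunable of the estimation chain with explicit per-stage
#' seeds derived from one master seed. The defaults reproduce the study
#' conditions: a 1000-draw uncertainty budget, a 10% trimming fraction in
#' the sex-ratio meta-regression, a 20-year cause-attribution cutoff, the
#' hearing-aid severity shift switched on, and disability-weight
#' uncertainty propagated.
#'
#' @param truth A [truth_config()] describing the synthetic world.
#' @param seed Master integer seed; stage seeds are fixed offsets of it.
#' @param n_per_stratum Survey respondents simulated per stratum.
#' @param n_draws Posterior draws per cell.
#' @param model_df Spline basis dimension of the prevalence models.
#' @param trim Trimming fraction of the sex-ratio meta-regression.
#' @param age_cutoff Cause-attribution age cutoff in years.
#' @param aid_adjustment Apply the hearing-aid severity shift.
#' @param dw_uncertainty Resample disability weights per draw.
#' @param forecast_years Projection years.
#' @param heterogeneity Fractions of locations whose survey rows exercise
#'   the harmonisation stage: `pool_sex` (both-sex rows), `alt_range`
#'   (moderate-plus reported as >= 30 dB), `wide_age` (25-year age bands).
#' @param keep_microdata Keep the simulated records in the manifest.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(truth = truth_config(), seed = 1L,
                            n_per_stratum = 1000L, n_draws = 1000L,
                            model_df = 8L, trim = 0.10, age_cutoff = 20,
                            aid_adjustment = TRUE, dw_uncertainty = TRUE,
                            forecast_years = c(2030L, 2040L, 2050L),
                            heterogeneity = list(pool_sex = 0.2,
                                                 alt_range = 0.2,
                                                 wide_age = 0.2),
                            keep_microdata = FALSE) {
  seed <- as.integer(seed)
  structure(list(
    truth = truth, seed = seed,
    seeds = list(truth = seed, microdata = seed + 1L, model = seed + 2L,
                 causes = seed + 3L, tinnitus = seed + 4L, dw = seed + 5L,
                 forecast = seed + 6L),
    n_per_stratum = as.integer(n_per_stratum), n_draws = as.integer(n_draws),
    model_df = as.integer(model_df), trim = trim, age_cutoff = age_cutoff,
    aid_adjustment = isTRUE(aid_adjustment),
    dw_uncertainty = isTRUE(dw_uncertainty),
    forecast_years = as.integer(forecast_years),
    heterogeneity = heterogeneity, keep_microdata = isTRUE(keep_microdata)
  ), class = "run_config")
}

# dB bands modelled: three top-level envelopes plus the five severities
pipeline_bands <- function() {
  list(normal = c(0, 20), mild = c(20, 35), mod_plus = c(35, Inf),
       moderate = c(35, 50), `moderately severe` = c(50, 65),
       severe = c(65, 80), profound = c(80, 95), complete = c(95, Inf))
}

# cheap deterministic fingerprint of an R object for the run manifest
manifest_checksum <- function(obj) {
  r <- serialize(obj, NULL, version = 2)
  v <- as.double(as.integer(r))
  sprintf("%012.0f", sum(v * (seq_along(v) %% 997 + 1)) %% 2^40)
}

#' Run the full estimation pipeline on the synthetic world
#'
#' Stages execute in order: simulate -> tabulate (with configurable
#' definitional heterogeneity) -> harmonise -> fit envelope models ->
#' top-level squeeze -> fit severity models -> envelope squeeze ->
#' hearing-aid coverage and shift -> cause attribution -> tinnitus split ->
#' burden (YLDs, aggregates, age-standardised rates, HAQ regression,
#' percentage changes) -> forecast. Identical configurations produce
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A run manifest: list with the stage outputs, a `summaries` list
#'   of headline quantities, and a `log` tibble (stage, rows, seed,
#'   checksum).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  log_rows <- list()
  note <- function(stage, obj, rows, seed = NA_integer_) {
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      stage = stage, rows = rows, seed = seed, checksum = manifest_checksum(obj))
  }

  truth <- make_truth(config$truth, config$seeds$truth)
  note("truth", truth$prevalence, nrow(truth$prevalence), config$seeds$truth)

  micro <- simulate_microdata(truth, config$n_per_stratum, config$seeds$microdata)
  note("simulate", nrow(micro), nrow(micro), config$seeds$microdata)

  survey <- pipeline_tabulate(micro, config)
  note("tabulate", survey, nrow(survey), NA_integer_)

  sex_model <- fit_sex_ratio(survey[survey$sex %in% c("female", "male"), ],
                             trim = config$trim)
  crosswalk <- fit_crosswalk(micro, alternative_ranges = list(c(30, Inf)),
                             reference_ranges = list(c(35, Inf)))
  processed <- process_survey_data(survey, sex_model = sex_model,
                                   crosswalk = crosswalk,
                                   age_pattern = truth$age_pattern,
                                   population = truth$population)
  note("process", processed, nrow(processed), NA_integer_)

  grid <- tidyr::crossing(truth$locations[c("location", "region")],
                          year = truth$config$years,
                          sex = c("female", "male"),
                          age_low = truth$config$age_lows)
  bands <- pipeline_bands()
  mc <- function(sign = NULL, offs = 0L) {
    model_config(df = config$model_df, covariates = "sdi",
                 covariate_sign = sign, n_draws = config$n_draws,
                 seed = config$seeds$model + offs)
  }
  fit_band <- function(name, sign = NULL, offs = 0L) {
    d <- processed[processed$db_low == bands[[name]][1] &
                     processed$db_high == bands[[name]][2], ]
    fit_category_model(d, mc(sign, offs), covariates = truth$covariates,
                       grid = grid[c("location", "year", "sex", "age_low")])
  }
  envelope_fits <- list(
    normal = fit_band("normal", offs = 0L),
    mild = fit_band("mild", offs = 10L),
    mod_plus = fit_band("mod_plus", sign = c(sdi = -1), offs = 20L)
  )
  top <- squeeze_top_level(envelope_fits$normal, envelope_fits$mild,
                           envelope_fits$mod_plus)
  sev_names <- severity_levels(moderate_plus = TRUE)
  sev_fits <- lapply(seq_along(sev_names), function(i) {
    fit_band(sev_names[i], offs = 30L + 10L * i)
  })
  names(sev_fits) <- sev_names
  sev_sq <- squeeze_severities(sev_fits, top$mod_plus)
  unadjusted <- stack_categories(c(list(normal = top$normal, mild = top$mild),
                                   sev_sq))
  note("estimate", ds_summary(unadjusted)$mean, nrow(unadjusted$keys),
       config$seeds$model)

  cov_obs <- tabulate_coverage(micro)
  coverage <- fit_coverage(cov_obs,
                           model_config(df = config$model_df, covariates = NULL,
                                        n_draws = config$n_draws,
                                        seed = config$seeds$model + 100L),
                           grid = grid[c("location", "year", "sex", "age_low")])
  adjusted <- if (config$aid_adjustment) {
    apply_aid_shift(unadjusted, coverage)
  } else {
    a <- unadjusted
    attr(a, "aid_adjusted") <- TRUE
    a
  }
  note("adjust", ds_summary(adjusted)$mean, nrow(adjusted$keys), NA_integer_)

  loss_sel <- as.character(adjusted$keys$category) != "normal"
  loss_surface <- draw_surface(adjusted$keys[loss_sel, , drop = FALSE],
                               adjusted$draws[loss_sel, , drop = FALSE])
  cause_models <- estimate_cause_models(
    micro, grid = grid[c("location", "year", "sex", "age_low")],
    n_draws = config$n_draws, seed = config$seeds$causes)
  cause_surface <- attribute_causes(loss_surface, cause_models,
                                    age_cutoff = config$age_cutoff)
  note("causes", ds_summary(cause_surface)$mean, nrow(cause_surface$keys),
       config$seeds$causes)

  tinnitus <- estimate_tinnitus(micro)
  states <- split_by_tinnitus(loss_surface, tinnitus,
                              seed = config$seeds$tinnitus)
  note("tinnitus", tinnitus, nrow(states$keys), config$seeds$tinnitus)

  burden <- compute_ylds(states, disability_weights(), truth$population,
                         dw_uncertainty = config$dw_uncertainty,
                         seed = config$seeds$dw)
  hierarchy <- truth$locations[c("location", "region")]
  summaries <- pipeline_summaries(config, truth, unadjusted, adjusted,
                                  cause_surface, burden, hierarchy)
  report <- report_severity_table(adjusted, truth$population, hierarchy,
                                  truth$standard_population,
                                  year = max(truth$config$years))
  note("burden", report, nrow(report), config$seeds$dw)

  fc <- pipeline_forecast(config, truth, adjusted, burden, hierarchy)
  note("forecast", fc$summary, nrow(fc$summary), config$seeds$forecast)
  summaries <- c(summaries, fc$headline)

  log <- dplyr::bind_rows(log_rows)
  out <- list(config = config, truth = truth, survey = survey,
              processed = processed, sex_model = sex_model,
              crosswalk = crosswalk, unadjusted = unadjusted,
              coverage = coverage, adjusted = adjusted,
              cause_surface = cause_surface, tinnitus = tinnitus,
              states = states, burden = burden, report = report,
              forecast = fc, summaries = summaries, log = log)
  if (config$keep_microdata) out$microdata <- micro
  class(out) <- "run_manifest"
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> stages:\n")
  print(x$log)
  invisible(x)
}

# tabulation with configurable definitional heterogeneity by location block
pipeline_tabulate <- function(micro, config) {
  locs <- sort(unique(micro$location))
  n <- length(locs)
  h <- config$heterogeneity
  n_pool <- floor(h$pool_sex * n)
  n_alt <- floor(h$alt_range * n)
  n_wide <- floor(h$wide_age * n)
  grp <- rep("standard", n)
  grp[seq_len(n_pool)] <- "pool_sex"
  grp[n_pool + seq_len(n_alt)] <- "alt_range"
  grp[n_pool + n_alt + seq_len(n_wide)] <- "wide_age"
  names(grp) <- locs

  bands <- pipeline_bands()
  tab_for <- function(records, g) {
    pool <- g == "pool_sex"
    ranges <- unname(bands)
    if (g == "alt_range") {
      ranges[[which(names(bands) == "mod_plus")]] <- c(30, Inf)
    }
    breaks <- if (g == "wide_age") seq(0, 95, by = 25) else sort(unique(records$age_low))
    tabulate_survey(records, age_breaks = breaks, db_ranges = ranges,
                    pool_sexes = pool)
  }
  out <- lapply(unique(grp), function(g) {
    sel <- micro$location %in% names(grp)[grp == g]
    tab_for(micro[sel, ], g)
  })
  dplyr::bind_rows(out)
}

pipeline_summaries <- function(config, truth, unadjusted, adjusted,
                               cause_surface, burden, hierarchy) {
  years <- truth$config$years
  y_last <- max(years)
  y_first <- min(years)
  pop <- truth$population
  std <- truth$standard_population

  cat_cases <- function(surface, members, year) {
    sel <- surface$keys$year == year &
      as.character(surface$keys$category) %in% members
    s <- draw_surface(surface$keys[sel, , drop = FALSE],
                      surface$draws[sel, , drop = FALSE])
    popv <- pop$pop[vctrs_match(s$keys[c("location", "year", "sex", "age_low")],
                                pop[c("location", "year", "sex", "age_low")])]
    colSums(s$draws * popv)
  }
  sev5 <- severity_levels(moderate_plus = TRUE)
  loss <- severity_levels(loss_only = TRUE)

  all_2019 <- cat_cases(adjusted, loss, y_last)
  mild_2019 <- cat_cases(adjusted, "mild", y_last)
  modp_adj_2019 <- cat_cases(adjusted, sev5, y_last)
  modp_unadj_2019 <- cat_cases(unadjusted, sev5, y_last)
  modp_adj_first <- cat_cases(adjusted, sev5, y_first)
  all_first <- cat_cases(adjusted, loss, y_first)

  pop_tot <- function(year) sum(pop$pop[pop$year == year])

  # age-standardised all-loss prevalence, global, per draw
  asr_loss <- function(surface, year) {
    sel <- surface$keys$year == year &
      as.character(surface$keys$category) %in% loss
    s <- draw_surface(surface$keys[sel, , drop = FALSE],
                      surface$draws[sel, , drop = FALSE])
    popv <- pop$pop[vctrs_match(s$keys[c("location", "year", "sex", "age_low")],
                                pop[c("location", "year", "sex", "age_low")])]
    num <- ds_sum_over(draw_surface(s$keys, s$draws * popv), "age_low")
    den <- rowsum(popv[as.character(s$keys$category) == loss[1]],
                  s$keys$age_low[as.character(s$keys$category) == loss[1]])
    ord <- match(as.character(num$keys$age_low), rownames(den))
    rate <- draw_surface(num$keys, num$draws / as.vector(den)[ord])
    as.vector(age_standardize(rate, std)$draws)
  }
  asr_2019 <- asr_loss(adjusted, y_last)
  asr_first <- asr_loss(adjusted, y_first)

  # YLDs: totals per draw
  yld_year <- function(year) {
    sel <- burden$keys$year == year
    colSums(burden$ylds[sel, , drop = FALSE])
  }
  yld_2019 <- yld_year(y_last)
  yld_first <- yld_year(y_first)
  yld_cat <- function(members, year) {
    sel <- burden$keys$year == year &
      as.character(burden$keys$category) %in% members
    colSums(burden$ylds[sel, , drop = FALSE])
  }
  yld_modp <- yld_cat(sev5, y_last)
  yld_mild <- yld_cat("mild", y_last)

  # HAQ regression: location-level age-standardised all-loss YLD rates per
  # 100 000 against the HAQ index in the final year
  sel <- burden$keys$year == y_last
  ylr <- draw_surface(burden$keys[sel, , drop = FALSE],
                      burden$yld_rate[sel, , drop = FALSE])
  ylr <- ds_sum_over(ylr, c("location", "age_low"))
  asr_yld_loc <- age_standardize(ylr, std)
  haq_df <- tibble::tibble(
    location = asr_yld_loc$keys$location,
    asr_yld = rowMeans(asr_yld_loc$draws) * 1e5
  )
  haq_df <- dplyr::left_join(
    haq_df, truth$covariates[truth$covariates$year == y_last,
                             c("location", "haq")], by = "location")
  haq <- haq_regression(haq_df)

  # under-5 otitis media share of hearing loss, from the cause surface
  u5 <- cause_surface$keys$age_low < 5
  u5_tot <- colSums(cause_surface$draws[u5, , drop = FALSE])
  u5_oti <- colSums(cause_surface$draws[
    u5 & cause_surface$keys$cause == "otitis_media", , drop = FALSE])
  under5_otitis <- 100 * u5_oti / u5_tot

  # share of the impaired older than 50, final year (case-weighted)
  sel50 <- adjusted$keys$year == y_last &
    as.character(adjusted$keys$category) %in% loss
  s50 <- draw_surface(adjusted$keys[sel50, , drop = FALSE],
                      adjusted$draws[sel50, , drop = FALSE])
  popv <- pop$pop[vctrs_match(s50$keys[c("location", "year", "sex", "age_low")],
                              pop[c("location", "year", "sex", "age_low")])]
  older <- s50$keys$age_low >= 50
  over50 <- 100 * colSums(s50$draws[older, , drop = FALSE] * popv[older]) /
    colSums(s50$draws * popv)

  list(
    all_loss_cases_2019 = summarize_draws(all_2019),
    all_loss_prevalence_pct_2019 = summarize_draws(100 * all_2019 / pop_tot(y_last)),
    mild_share_pct_2019 = summarize_draws(100 * mild_2019 / all_2019),
    modplus_adjusted_cases_2019 = summarize_draws(modp_adj_2019),
    modplus_unadjusted_cases_2019 = summarize_draws(modp_unadj_2019),
    modplus_cases_first_year = summarize_draws(modp_adj_first),
    pct_change_modplus = percent_change(modp_adj_first, modp_adj_2019),
    crude_prev_pct_first = summarize_draws(100 * all_first / pop_tot(y_first)),
    asr_all_loss_pct_2019 = summarize_draws(100 * asr_2019),
    asr_all_loss_pct_first = summarize_draws(100 * asr_first),
    ylds_2019 = summarize_draws(yld_2019),
    pct_change_ylds = percent_change(yld_first, yld_2019),
    yld_share_modplus_pct = summarize_draws(100 * yld_modp / (yld_modp + yld_mild)),
    under5_otitis_share_pct = summarize_draws(under5_otitis),
    over50_share_pct = summarize_draws(over50),
    haq_adj_r2 = haq$adj_r2,
    haq_slope = haq$slope,
    draws = list(all_loss_cases_2019 = all_2019,
                 modplus_adjusted_cases_2019 = modp_adj_2019)
  )
}

pipeline_forecast <- function(config, truth, adjusted, burden, hierarchy) {
  years <- truth$config$years
  pop <- truth$population
  loss <- severity_levels(loss_only = TRUE)
  sev5 <- severity_levels(moderate_plus = TRUE)

  region_rates <- function(members) {
    sel <- as.character(adjusted$keys$category) %in% members
    s <- draw_surface(adjusted$keys[sel, , drop = FALSE],
                      adjusted$draws[sel, , drop = FALSE])
    popv <- pop$pop[vctrs_match(s$keys[c("location", "year", "sex", "age_low")],
                                pop[c("location", "year", "sex", "age_low")])]
    k <- s$keys
    k$region <- hierarchy$region[match(k$location, hierarchy$location)]
    num <- ds_sum_over(draw_surface(k, s$draws * popv),
                       c("region", "year", "sex", "age_low"))
    den <- rowsum(popv[as.character(s$keys$category) == members[1]],
                  paste(k$region, k$year, k$sex, k$age_low)[
                    as.character(s$keys$category) == members[1]])
    ord <- match(paste(num$keys$region, num$keys$year, num$keys$sex,
                       num$keys$age_low), rownames(den))
    out <- num$keys
    out$rate <- rowMeans(num$draws) / as.vector(den)[ord]
    out
  }
  pop_fc <- make_population(truth$config, truth$locations,
                            config$forecast_years)
  run_fc <- function(members, offs) {
    rates <- region_rates(members)
    model <- fit_forecast(rates, resamples = config$n_draws,
                          seed = config$seeds$forecast + offs)
    project(model, config$forecast_years, pop_fc)
  }
  fc_all <- run_fc(loss, 0L)
  fc_modp <- run_fc(sev5, 1L)

  y_last <- max(years)
  base_all <- colSums(
    {sel <- burden$keys$year == y_last; burden$cases[sel, , drop = FALSE]})
  glob <- function(fc, yr) {
    sel <- fc$cases$keys$region == "global" & fc$cases$keys$year == yr
    as.vector(fc$cases$cases[sel, , drop = FALSE])
  }
  y_fc <- max(config$forecast_years)
  all_2050 <- glob(fc_all, y_fc)
  modp_2050 <- glob(fc_modp, y_fc)

  summary <- dplyr::bind_cols(fc_modp$cases$keys,
                              summarize_draws(fc_modp$cases$cases))
  headline <- list(
    forecast_all_loss_cases_final = summarize_draws(all_2050),
    forecast_modplus_cases_final = summarize_draws(modp_2050),
    pct_increase_all_loss_to_final = percent_change(base_all, all_2050)
  )
  list(all_loss = fc_all, mod_plus = fc_modp, summary = summary,
       headline = headline, base_all_loss_2019 = base_all)
}
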