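test_that("generators are pure functions of the seed", {
  cfg <- scenario_config(seed = 5, n_respondents = 400, n_cities = 2,
                         tracts_per_city = 3, years = 2011:2012)
  expect_identical(simulate_survey(cfg), simulate_survey(cfg))
  p1 <- simulate_area_profiles(cfg)
  expect_identical(p1, simulate_area_profiles(cfg))
  tc <- structure(list(intercept = cfg$true_logit_coefs$intercept,
                       coefficients = cfg$true_logit_coefs$coefficients),
                  class = "smi_logit")
  prev <- project_all(tc, p1[setdiff(names(p1), c("city_id", "precinct_id"))])
  c1 <- simulate_event_counts(cfg, prev, p1)
  expect_identical(c1, simulate_event_counts(cfg, prev, p1))
  # a different seed changes the data
  cfg2 <- scenario_config(seed = 6, n_respondents = 400, n_cities = 2,
                          tracts_per_city = 3, years = 2011:2012)
  expect_false(identical(simulate_survey(cfg2)$days_unable_to_function,
                         simulate_survey(cfg)$days_unable_to_function))
})

test_that("back-filled survey items reproduce the latent label exactly", {
  cfg <- scenario_config(seed = 8, n_respondents = 3000)
  sv <- simulate_survey(cfg)
  expect_identical(classify_smi(sv), attr(sv, "latent_smi"))
  # and through the table interface
  lab <- classify_survey(sv)
  expect_identical(lab$smi, attr(sv, "latent_smi"))
})

test_that("an intercept-only scenario hits its Bernoulli rate", {
  coefs <- default_true_logit_coefs()
  coefs$intercept <- -4.33
  coefs$coefficients[] <- 0
  cfg <- scenario_config(seed = 13, n_respondents = 50000,
                         true_logit_coefs = coefs)
  sv <- simulate_survey(cfg)
  # binomial MC error at n = 50,000: SE ~ 0.05pp, tolerance 0.15pp
  expect_lt(abs(mean(attr(sv, "latent_smi")) - stats::plogis(-4.33)), 0.0015)
})

test_that("area profiles satisfy the indicator-proportion invariants", {
  cfg <- scenario_config(seed = 9, n_cities = 3, tracts_per_city = 4,
                         years = 2011:2013)
  prof <- simulate_area_profiles(cfg)
  expect_identical(nrow(prof), 3L * 4L * 3L)
  sc <- default_coding_scheme()
  for (nm in names(sc$covariates)) {
    cv <- sc$covariates[[nm]]
    if (cv$kind != "categorical") next
    cols <- paste(nm, setdiff(cv$levels, cv$reference), sep = "_")
    s <- rowSums(prof[cols])
    # implicit reference proportion 1 - s stays on the simplex
    expect_true(all(s >= 0 & s <= 1 + 1e-6))
    expect_true(all(prof[cols] >= 0 & prof[cols] <= 1))
  }
  expect_true(all(prof$adult_population >= cfg$pop_range[1] &
                    prof$adult_population <= cfg$pop_range[2]))
})

test_that("zero tract jitter makes every tract the population distribution", {
  cfg <- scenario_config(seed = 10, n_cities = 2, tracts_per_city = 3,
                         years = 2011, tract_jitter = 0)
  prof <- simulate_area_profiles(cfg)
  dists <- cfg$covariate_distributions
  expect_true(all(abs(prof$race_Black - dists$race$probs[["Black"]]) < 1e-12))
  expect_true(all(abs(prof$poverty_index - dists$poverty_index$mean) < 1e-12))
  # identical linear predictors -> identical projected prevalence
  tc <- structure(list(intercept = cfg$true_logit_coefs$intercept,
                       coefficients = cfg$true_logit_coefs$coefficients),
                  class = "smi_logit")
  prev <- project_all(tc, prof[setdiff(names(prof), c("city_id", "precinct_id"))])
  expect_lt(diff(range(prev$p_smi)), 1e-12)
})

test_that("event counts follow the generative moment identities", {
  # Poisson-limit, no area effects, RR 1: cell means = exposure x rate x year
  cfg <- scenario_config(seed = 14, n_cities = 2, tracts_per_city = 2,
                         years = 2011:2012, sigma_beta_true = 0,
                         phi_true = 1e6, true_rr_smi = 1, tract_jitter = 0,
                         base_rate = 0.02)
  prev <- data.frame(area_id = rep(c("c01_t01", "c01_t02"), 2),
                     year = rep(2011:2012, each = 2),
                     n_smi = 1e5, n_nosmi = 1e5)
  reps <- do.call(rbind, lapply(1:300, function(r) {
    cfg_r <- cfg; cfg_r$seed <- 1000L + r
    simulate_event_counts(cfg_r, prev, NULL)
  }))
  f <- reps[reps$outcome == "force" & reps$year == 2011, ]
  mu <- 1e5 * 0.02
  expect_equal(mean(f$y), mu, tolerance = 0.01)
  f2 <- reps[reps$outcome == "force" & reps$year == 2012, ]
  expect_equal(mean(f2$y), mu * exp(cfg$true_year_effects[["2012"]]),
               tolerance = 0.01)

  # RR identity: total SMI events / total non-SMI events ~ RR x exposure ratio
  sc <- small_count_scenario(seed = 15, true_rr = 11.6, sigma_beta = 0.5)
  f <- sc$counts[sc$counts$outcome == "force", ]
  smi <- f[f$group == "SMI", ]; ns <- f[f$group == "non_SMI", ]
  # compare like cells so shared area/year effects cancel
  expect_equal(sum(smi$y) / sum(ns$y * 11.6 * smi$exposure / ns$exposure), 1,
               tolerance = 0.15)
})

test_that("the incident table aggregates back to the count table exactly", {
  fx <- get_fixture()
  sc <- fx$counts[fx$counts$grouping == "smi_status", ]
  agg <- stats::aggregate(
    list(y = rep(1L, nrow(fx$incidents))),
    by = list(area_id = fx$incidents$area_id, year = fx$incidents$year,
              outcome = fx$incidents$outcome,
              group = ifelse(fx$incidents$smi_flag, "SMI", "non_SMI")),
    FUN = sum)
  m <- merge(sc, agg, by = c("area_id", "year", "outcome", "group"),
             all.x = TRUE, suffixes = c("", "_inc"))
  m$y_inc[is.na(m$y_inc)] <- 0L
  expect_identical(as.integer(m$y), as.integer(m$y_inc))
})

test_that("label noise flips only SMI-involved incidents to non-SMI", {
  cfg <- scenario_config(seed = 16, n_cities = 2, tracts_per_city = 3,
                         years = 2011:2012, label_noise = 0.3)
  sc0 <- small_count_scenario(seed = 16, true_rr = 10, n_cities = 2, tracts = 3,
                              years = 2011:2012)
  inc_clean <- simulate_incidents(sc0$config, sc0$counts)
  inc_noisy <- simulate_incidents(cfg, sc0$counts)
  expect_identical(nrow(inc_clean), nrow(inc_noisy))
  expect_lt(sum(inc_noisy$smi_flag), sum(inc_clean$smi_flag))
  expect_true(all(inc_clean$smi_flag | !inc_noisy$smi_flag))
})

test_that("the paper-like fixture bundle is internally consistent", {
  fx <- get_fixture()
  expect_identical(nrow(fx$survey), 5493L)
  expect_identical(length(unique(fx$mapping$city_id)), 9L)
  expect_identical(nrow(fx$profiles), 9L * 12L * 7L)
  expect_true(all(fx$counts$y >= 0))
  expect_true(all(fx$prevalence_true$p_smi > 0 & fx$prevalence_true$p_smi < 1))
  expect_identical(fx$truth$rr_smi, 11.6)
  expect_identical(unname(fx$truth$rr_race["Black"]), 3.1)
  # every generating parameter is on the truth record
  expect_true(all(c("rr_smi", "rr_race", "year_effects", "sigma_beta",
                    "phi", "base_rate", "logit_coefs", "beta_areas")
                  %in% names(fx$truth)))
  expect_identical(length(fx$truth$beta_areas), 108L)
})

test_that("scenario configs validate their inputs", {
  expect_error(scenario_config(years = c(2012, 2011)), "ascending")
  expect_error(scenario_config(true_year_effects = c("2011" = 0.5),
                               years = 2011), "must be 0")
  bad <- default_covariate_distributions()
  bad$race$probs <- c(White = 0.9, Black = 0.5, Latinx = 0.1, Other = 0.1)
  expect_error(scenario_config(covariate_distributions = bad), "sum to 1")
})
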