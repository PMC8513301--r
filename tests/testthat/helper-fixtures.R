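# Shared fixtures and small oracles, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# The default paper-like bundle (9 cities x 12 tracts x 7 years), cached.
get_fixture <- function(seed = 101) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_paper_like_fixture(seed = seed)
  }
  .fixture_cache[[key]]
}

# A minimal single-respondent survey row; items default to the all-zero
# (clearly non-SMI) state and are overridden by name.
survey_row <- function(id = "r1", diagnoses = character(), days = 0,
                       ratings = c(0, 0, 0, 0), duration = 0) {
  row <- data.frame(respondent_id = id, stringsAsFactors = FALSE)
  for (k in smi_diagnosis_catalogue()) {
    row[[paste0("diag_", k)]] <- as.integer(k %in% diagnoses)
  }
  row$days_unable_to_function <- days
  row$imp_work <- ratings[1]; row$imp_home <- ratings[2]
  row$imp_relationships <- ratings[3]; row$imp_social <- ratings[4]
  row$disorder_duration_months <- duration
  row
}

# Independent maximum-likelihood oracle for the logistic fit: quasi-Newton
# maximization of the hand-written Bernoulli log-likelihood with analytic
# gradient. Shares no code with fit_smi_logit's IRLS path.
logit_mle_oracle <- function(X, y, weights = rep(1, length(y))) {
  Xi <- cbind(1, X)
  nll <- function(b) {
    eta <- drop(Xi %*% b)
    -sum(weights * (y * eta - log1p(exp(eta))))
  }
  gr <- function(b) {
    p <- stats::plogis(drop(Xi %*% b))
    -drop(crossprod(Xi, weights * (y - p)))
  }
  o <- stats::optim(rep(0, ncol(Xi)), nll, gr, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-15))
  o$par
}

# Posterior median and Monte Carlo standard error for one parameter.
draw_stat <- function(draws, param) {
  v <- draws$draws[, param]
  ml <- coda::as.mcmc.list(lapply(split(v, draws$chain), coda::as.mcmc))
  ess <- unname(coda::effectiveSize(ml))
  c(median = stats::median(v), mean = mean(v), sd = stats::sd(v),
    mcse = stats::sd(v) / sqrt(max(ess, 1)))
}

# Wrap a posterior_draws-shaped object around externally supplied draws of
# a single group coefficient, for testing summarize_disparity in isolation.
fake_group_draws <- function(alpha, chains = 2) {
  n <- length(alpha)
  md <- list(group_levels = "SMI", year_levels = integer(),
             reference_group = "non_SMI", reference_year = 2011L,
             y = integer(4), area_levels = c("a1", "a2"))
  structure(list(draws = cbind(alpha_SMI = alpha,
                               sigma_beta = rep(1, n), phi = rep(1, n)),
                 chain = rep(seq_len(chains), each = n / chains),
                 draw = rep(seq_len(n / chains), times = chains),
                 model_data = md,
                 config = disparity_config()),
            class = "posterior_draws")
}

# Small count scenario (50 tracts x 3 years) used by the sampler tests.
small_count_scenario <- function(seed, true_rr = 1, sigma_beta = 1,
                                 phi = 1.2, n_cities = 10, tracts = 5,
                                 years = 2011:2013) {
  cfg <- scenario_config(seed = seed, n_cities = n_cities,
                         tracts_per_city = tracts, years = years,
                         true_rr_smi = true_rr, sigma_beta_true = sigma_beta,
                         phi_true = phi)
  prof <- simulate_area_profiles(cfg)
  tc <- structure(list(intercept = cfg$true_logit_coefs$intercept,
                       coefficients = cfg$true_logit_coefs$coefficients),
                  class = "smi_logit")
  prev <- project_all(tc, prof[setdiff(names(prof), c("city_id", "precinct_id"))])
  counts <- simulate_event_counts(cfg, prev, NULL)
  list(config = cfg, profiles = prof, prevalence = prev, counts = counts)
}
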