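#' Default covariate distributions for the synthetic survey population
#'
#' Category probabilities and continuous-moment defaults chosen to resemble
#' the adult population of moderately sized US cities.
#'
#' @return Named list, one element per covariate of
#'   [default_coding_scheme()].
#' @export
default_covariate_distributions <- function() {
  list(
    age_category = list(kind = "categorical",
                        probs = c("18_29" = 0.22, "30_44" = 0.27,
                                  "45_59" = 0.26, "60_plus" = 0.25)),
    gender = list(kind = "categorical",
                  probs = c(male = 0.48, female = 0.52)),
    race = list(kind = "categorical",
                probs = c(White = 0.62, Black = 0.13, Latinx = 0.17,
                          Other = 0.08)),
    marital_status = list(kind = "categorical",
                          probs = c(married = 0.52, never_married = 0.28,
                                    prev_married = 0.20)),
    employment_status = list(kind = "categorical",
                             probs = c(employed = 0.62, unemployed = 0.06,
                                       not_in_labor_force = 0.32)),
    education = list(kind = "categorical",
                     probs = c(lt_highschool = 0.13, highschool = 0.28,
                               some_college = 0.29, college = 0.30)),
    poverty_index = list(kind = "continuous", mean = 2.5, sd = 1.2)
  )
}

#' Default true logistic coefficients for latent SMI
#'
#' Log-odds effects with epidemiologically plausible signs (higher SMI odds
#' for women, the unemployed, the never/previously married; lower for
#' older adults, the college-educated, and higher income-to-poverty
#' ratios). The intercept is set so that plug-in prevalence at typical
#' covariate profiles falls near 2%, inside the 1-3.5% band realistic for
#' US cities.
#'
#' @return List with `intercept` and named `coefficients` aligned to
#'   [default_coding_scheme()] design columns.
#' @export
default_true_logit_coefs <- function() {
  list(intercept = -3.55,
       coefficients = c(
         age_category_30_44 = 0.10, age_category_45_59 = 0.00,
         age_category_60_plus = -0.80,
         gender_female = 0.35,
         race_Black = -0.10, race_Latinx = 0.00, race_Other = -0.20,
         marital_status_never_married = 0.50,
         marital_status_prev_married = 0.40,
         employment_status_unemployed = 0.80,
         employment_status_not_in_labor_force = 0.40,
         education_highschool = -0.20, education_some_college = -0.30,
         education_college = -0.60,
         poverty_index = -0.15))
}

default_year_effects <- function(years) {
  stats::setNames(c(0, rep_len(c(-0.14, 0.29, 0.28, 0.18, 0.02, 0.10),
                               length(years) - 1L)),
                  as.character(years))
}

#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every generating parameter of the full forward model: survey
#' covariate distributions and true logistic coefficients for latent SMI,
#' the area/tract layout, and the count-model truths (relative risks, year
#' effects, area-effect SD, dispersion, baseline event rate). Defaults are
#' the package's paper-like scenario: 9 cities, 12 tracts each, years
#' 2011-2017, a ~2% SMI prevalence, RR 11.6 for SMI status, RR 3.1 / 1.0
#' for Black / Latinx vs White, sigma_beta 1.5, phi 1.2.
#'
#' @param seed Integer master seed; every generator op derives its stream
#'   from it deterministically.
#' @param n_respondents Survey size (default 5493).
#' @param n_cities,tracts_per_city Area layout (defaults 9 and 12).
#' @param years Calendar years, ascending (default 2011:2017).
#' @param true_logit_coefs List with `intercept` and named `coefficients`
#'   (see [default_true_logit_coefs()]).
#' @param covariate_distributions See [default_covariate_distributions()].
#' @param true_rr_smi True SMI-vs-non-SMI relative risk (default 11.6).
#' @param true_rr_race Named vector of race relative risks vs White
#'   (default Black 3.1, Latinx 1.0, Other 1.0).
#' @param true_year_effects Named log-scale year effects; first year must
#'   be 0. `NULL` uses a fixed paper-like pattern.
#' @param sigma_beta_true SD of area (tract) log-rate effects (default 1.5).
#' @param phi_true NB dispersion (default 1.2).
#' @param base_rate Force events per person-year in the reference group of
#'   a median area (default 0.0016, giving ~25k incidents at the default
#'   layout).
#' @param injury_rate_scale Injury baseline as a fraction of the force
#'   baseline (default 0.3); group/year/area effects are shared.
#' @param pop_range Tract adult-population range (uniform; default
#'   1200-8000).
#' @param tract_jitter SD of tract-level log-perturbations of covariate
#'   distributions (0 = identical tracts; default 0.15).
#' @param label_noise Probability an SMI-involved incident is recorded as
#'   non-SMI (officer-style false negatives; default 0).
#' @param homeless_per_city Optional homeless count per city (default 0),
#'   consumed by [adjust_prevalence_homeless()].
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_respondents = 5493L,
                            n_cities = 9L,
                            tracts_per_city = 12L,
                            years = 2011:2017,
                            true_logit_coefs = default_true_logit_coefs(),
                            covariate_distributions = default_covariate_distributions(),
                            true_rr_smi = 11.6,
                            true_rr_race = c(Black = 3.1, Latinx = 1.0, Other = 1.0),
                            true_year_effects = NULL,
                            sigma_beta_true = 1.5,
                            phi_true = 1.2,
                            base_rate = 0.0016,
                            injury_rate_scale = 0.3,
                            pop_range = c(1200, 8000),
                            tract_jitter = 0.15,
                            label_noise = 0,
                            homeless_per_city = 0) {
  if (is.unsorted(years, strictly = TRUE)) {
    stop("years must be strictly ascending", call. = FALSE)
  }
  for (nm in names(covariate_distributions)) {
    cd <- covariate_distributions[[nm]]
    if (cd$kind == "categorical" &&
        abs(sum(cd$probs) - 1) > 1e-8) {
      stop(sprintf("covariate '%s': category probabilities must sum to 1", nm),
           call. = FALSE)
    }
  }
  if (is.null(true_year_effects)) true_year_effects <- default_year_effects(years)
  if (!identical(names(true_year_effects), as.character(years))) {
    stop("true_year_effects must be named by the scenario years", call. = FALSE)
  }
  if (true_year_effects[[1L]] != 0) {
    stop("the first (reference) year effect must be 0", call. = FALSE)
  }
  stopifnot(true_rr_smi > 0, all(true_rr_race > 0), sigma_beta_true >= 0,
            phi_true > 0, base_rate > 0, label_noise >= 0, label_noise <= 1)
  structure(list(seed = as.integer(seed), n_respondents = as.integer(n_respondents),
                 n_cities = as.integer(n_cities),
                 tracts_per_city = as.integer(tracts_per_city),
                 years = as.integer(years),
                 true_logit_coefs = true_logit_coefs,
                 covariate_distributions = covariate_distributions,
                 true_rr_smi = true_rr_smi, true_rr_race = true_rr_race,
                 true_year_effects = true_year_effects,
                 sigma_beta_true = sigma_beta_true, phi_true = phi_true,
                 base_rate = base_rate, injury_rate_scale = injury_rate_scale,
                 pop_range = pop_range, tract_jitter = tract_jitter,
                 label_noise = label_noise,
                 homeless_per_city = homeless_per_city),
            class = "scenario_config")
}

with_stage_seed <- function(config, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((config$seed * 97L + offset) %% 2147483647L)
  expr
}

#' Simulate survey microdata with a known latent SMI label
#'
#' Draws demographic covariates from the scenario's distributions, draws
#' latent SMI as Bernoulli(inverse-logit of the true linear predictor),
#' then back-fills the diagnostic, impairment, and duration items so that
#' [classify_smi()] reproduces the latent label exactly: SMI rows receive
#' a catalogue diagnosis, a duration of at least 12 months, and either
#' >=120 impaired days or a domain rating >=7; non-SMI rows violate at
#' least one criterion (most have no diagnosis; the rest fail the
#' impairment or duration threshold).
#'
#' @param config A [scenario_config()].
#' @return Survey data frame (one row per respondent) with an attribute
#'   `latent_smi` carrying the generating label.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_stage_seed(config, 1L, {
    n <- config$n_respondents
    dists <- config$covariate_distributions
    cov <- list()
    for (nm in names(dists)) {
      cd <- dists[[nm]]
      cov[[nm]] <- if (cd$kind == "categorical") {
        sample(names(cd$probs), n, replace = TRUE, prob = cd$probs)
      } else {
        pmax(stats::rnorm(n, cd$mean, cd$sd), 0)
      }
    }
    survey <- data.frame(respondent_id = sprintf("r%05d", seq_len(n)),
                         stringsAsFactors = FALSE)
    for (nm in names(cov)) survey[[nm]] <- cov[[nm]]

    tc <- config$true_logit_coefs
    lp <- rep(tc$intercept, n)
    for (cn in names(tc$coefficients)) {
      b <- tc$coefficients[[cn]]
      if (b == 0) next
      if (cn %in% names(survey)) {
        lp <- lp + b * survey[[cn]]
      } else {
        # design columns are named variable_level; recover by prefix match
        var <- NULL
        for (nm in names(dists)) {
          if (startsWith(cn, paste0(nm, "_"))) { var <- nm; break }
        }
        if (is.null(var)) stop(sprintf("coefficient '%s' matches no covariate", cn),
                               call. = FALSE)
        lev <- substring(cn, nchar(var) + 2L)
        lp <- lp + b * (survey[[var]] == lev)
      }
    }
    smi <- stats::runif(n) < stats::plogis(lp)

    catalogue <- smi_diagnosis_catalogue()
    for (k in catalogue) survey[[paste0("diag_", k)]] <- 0L
    survey$days_unable_to_function <- 0L
    survey$imp_work <- 0L; survey$imp_home <- 0L
    survey$imp_relationships <- 0L; survey$imp_social <- 0L
    survey$disorder_duration_months <- 0L
    imp_cols <- impairment_columns()

    idx_smi <- which(smi)
    if (length(idx_smi)) {
      dg <- sample(catalogue, length(idx_smi), replace = TRUE)
      for (k in unique(dg)) {
        survey[[paste0("diag_", k)]][idx_smi[dg == k]] <- 1L
      }
      survey$disorder_duration_months[idx_smi] <-
        sample(12:240, length(idx_smi), replace = TRUE)
      via_days <- stats::runif(length(idx_smi)) < 0.5
      i_days <- idx_smi[via_days]; i_rate <- idx_smi[!via_days]
      survey$days_unable_to_function[i_days] <-
        sample(120:365, length(i_days), replace = TRUE)
      for (ic in imp_cols) {
        survey[[ic]][i_days] <- sample(0:6, length(i_days), replace = TRUE)
      }
      if (length(i_rate)) {
        survey$days_unable_to_function[i_rate] <-
          sample(0:119, length(i_rate), replace = TRUE)
        for (ic in imp_cols) {
          survey[[ic]][i_rate] <- sample(0:6, length(i_rate), replace = TRUE)
        }
        dom <- sample(imp_cols, length(i_rate), replace = TRUE)
        for (ic in imp_cols) {
          sel <- i_rate[dom == ic]
          survey[[ic]][sel] <- sample(7:10, length(sel), replace = TRUE)
        }
      }
    }
    idx_no <- which(!smi)
    if (length(idx_no)) {
      mode <- sample(c("no_diag", "fail_impair", "fail_duration"),
                     length(idx_no), replace = TRUE, prob = c(0.80, 0.12, 0.08))
      i_fi <- idx_no[mode == "fail_impair"]
      i_fd <- idx_no[mode == "fail_duration"]
      for (sel in list(i_fi, i_fd)) {
        if (!length(sel)) next
        dg <- sample(catalogue, length(sel), replace = TRUE)
        for (k in unique(dg)) survey[[paste0("diag_", k)]][sel[dg == k]] <- 1L
      }
      # fail criterion B: mild items, duration can qualify
      survey$days_unable_to_function[i_fi] <- sample(0:119, length(i_fi), replace = TRUE)
      for (ic in imp_cols) survey[[ic]][i_fi] <- sample(0:6, length(i_fi), replace = TRUE)
      survey$disorder_duration_months[i_fi] <- sample(12:60, length(i_fi), replace = TRUE)
      # fail criterion C: short duration, items free
      survey$days_unable_to_function[i_fd] <- sample(0:365, length(i_fd), replace = TRUE)
      for (ic in imp_cols) survey[[ic]][i_fd] <- sample(0:10, length(i_fd), replace = TRUE)
      survey$disorder_duration_months[i_fd] <- sample(0:11, length(i_fd), replace = TRUE)
      # no diagnosis: low-grade items
      i_nd <- idx_no[mode == "no_diag"]
      survey$days_unable_to_function[i_nd] <- sample(0:60, length(i_nd), replace = TRUE)
      for (ic in imp_cols) survey[[ic]][i_nd] <- sample(0:6, length(i_nd), replace = TRUE)
      survey$disorder_duration_months[i_nd] <- sample(0:24, length(i_nd), replace = TRUE)
    }
    survey$weight <- 1
    attr(survey, "latent_smi") <- as.logical(smi)
    survey
  })
}

#' Simulate tract-level area covariate profiles
#'
#' One row per tract-year. Tract adult populations are uniform over the
#' scenario's `pop_range`; each tract's covariate distribution is a
#' log-perturbation of the survey-level distribution (`tract_jitter = 0`
#' makes every tract identical to it), renormalized so that indicator
#' proportions within each categorical variable, including the implicit
#' reference level, sum to one. Tract profiles are held constant across
#' years.
#'
#' @param config A [scenario_config()].
#' @return Data frame: `area_id`, `city_id`, `precinct_id`, `geography`
#'   (`"tract"`), `year`, `adult_population`, then one column per design
#'   column of [default_coding_scheme()].
#' @export
simulate_area_profiles <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_stage_seed(config, 2L, {
    dists <- config$covariate_distributions
    scheme_cols <- design_columns(default_coding_scheme())
    rows <- list()
    for (ci in seq_len(config$n_cities)) {
      for (ti in seq_len(config$tracts_per_city)) {
        tract <- sprintf("c%02d_t%02d", ci, ti)
        pop <- round(stats::runif(1, config$pop_range[1L], config$pop_range[2L]))
        vals <- list()
        for (nm in names(dists)) {
          cd <- dists[[nm]]
          if (cd$kind == "categorical") {
            p <- cd$probs
            if (config$tract_jitter > 0) {
              p <- p * exp(stats::rnorm(length(p), 0, config$tract_jitter))
              p <- p / sum(p)
            }
            for (lv in names(p)) vals[[paste(nm, lv, sep = "_")]] <- unname(p[[lv]])
          } else {
            m <- cd$mean
            if (config$tract_jitter > 0) {
              m <- max(m + stats::rnorm(1, 0, config$tract_jitter * cd$sd), 0)
            }
            vals[[nm]] <- m
          }
        }
        row <- data.frame(area_id = tract, city_id = sprintf("c%02d", ci),
                          precinct_id = sprintf("c%02d_p%02d", ci, ceiling(ti / 3)),
                          geography = "tract", stringsAsFactors = FALSE)
        for (cl in scheme_cols) row[[cl]] <- vals[[cl]]
        row$adult_population <- pop
        rows[[length(rows) + 1L]] <- row
      }
    }
    base <- do.call(rbind, rows)
    out <- do.call(rbind, lapply(config$years, function(yr) {
      b <- base; b$year <- yr; b
    }))
    out <- out[c("area_id", "city_id", "precinct_id", "geography", "year",
                 "adult_population", scheme_cols)]
    out <- out[order(out$area_id, out$year), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate event-count tables from the generative count model
#'
#' Runs the hierarchical negative-binomial model forward: one area effect
#' `beta_i ~ Normal(0, sigma_beta_true^2)` per tract; cell mean
#' `mu = exposure x base_rate x RR(group) x exp(year effect) x exp(beta_i)`
#' (injury cells use `base_rate x injury_rate_scale`); counts drawn
#' NB(mu, phi_true). Emits both the SMI-status table (exposures `n_smi` /
#' `n_nosmi` from the supplied prevalence) and the race table (exposures
#' from the profiles' race mix of the adult population).
#'
#' @param config A [scenario_config()].
#' @param prevalence Tract-level prevalence table (`area_id`, `year`,
#'   `n_smi`, `n_nosmi`), typically the truth from projecting
#'   `true_logit_coefs` onto the profiles.
#' @param profiles Tract profiles from [simulate_area_profiles()]
#'   (required for the race table; `NULL` skips it).
#' @return Data frame: `area_id`, `city_id`, `geography`, `year`,
#'   `grouping` (`smi_status`/`race`), `group`, `outcome`, `y`,
#'   `exposure`; attribute `beta_true` carries the drawn area effects.
#' @export
simulate_event_counts <- function(config, prevalence, profiles = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  need <- c("area_id", "year", "n_smi", "n_nosmi")
  missing <- setdiff(need, names(prevalence))
  if (length(missing)) {
    stop("prevalence missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(setdiff(config$years, unique(prevalence$year)))) {
    stop("prevalence does not cover every scenario year", call. = FALSE)
  }
  with_stage_seed(config, 3L, {
    areas <- sort(unique(prevalence$area_id))
    beta <- stats::setNames(stats::rnorm(length(areas), 0, config$sigma_beta_true),
                            areas)
    year_mult <- exp(config$true_year_effects)
    city_of <- function(a) sub("_.*$", "", a)
    draw_cells <- function(grouping, group, exposure_by_cell, rr) {
      base <- prevalence[c("area_id", "year")]
      out <- list()
      for (outcome in c("force", "injury")) {
        rate <- config$base_rate *
          (if (outcome == "injury") config$injury_rate_scale else 1)
        mu <- exposure_by_cell * rate * rr *
          year_mult[as.character(base$year)] * exp(beta[base$area_id])
        y <- integer(length(mu))
        pos <- exposure_by_cell > 0
        y[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = config$phi_true)
        out[[outcome]] <- data.frame(
          area_id = base$area_id, city_id = city_of(base$area_id),
          geography = "tract", year = base$year, grouping = grouping,
          group = group, outcome = outcome, y = y,
          exposure = exposure_by_cell, stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }
    tabs <- list(
      draw_cells("smi_status", "non_SMI", prevalence$n_nosmi, 1),
      draw_cells("smi_status", "SMI", prevalence$n_smi, config$true_rr_smi)
    )
    if (!is.null(profiles)) {
      prof <- merge(prevalence[c("area_id", "year")], profiles,
                    by = c("area_id", "year"), sort = FALSE)
      race_levels <- c("White", names(config$true_rr_race))
      for (r in race_levels) {
        col <- paste0("race_", r)
        prop <- if (r == "White") {
          1 - prof$race_Black - prof$race_Latinx - prof$race_Other
        } else {
          prof[[col]]
        }
        rr <- if (r == "White") 1 else unname(config$true_rr_race[[r]])
        tabs[[length(tabs) + 1L]] <-
          draw_cells("race", r, prop * prof$adult_population, rr)
      }
    }
    counts <- do.call(rbind, tabs)
    counts <- counts[order(counts$grouping, counts$outcome, counts$area_id,
                           counts$year, counts$group), ]
    rownames(counts) <- NULL
    attr(counts, "beta_true") <- beta
    counts
  })
}

#' Expand SMI-status counts into an incident-level table
#'
#' One row per incident, attributes drawn from the aggregated cell it came
#' from; with `label_noise = 0` (the default) aggregating the incident
#' table reproduces the SMI-status count table exactly. Positive
#' `label_noise` flips SMI-involved incidents to non-SMI with that
#' probability, emulating officers' tendency to miss serious mental
#' illness rather than over-attribute it.
#'
#' @param config A [scenario_config()].
#' @param counts Output of [simulate_event_counts()].
#' @return Data frame: `city_id`, `area_id`, `year`, `outcome`, `smi_flag`.
#' @export
simulate_incidents <- function(config, counts) {
  stopifnot(inherits(config, "scenario_config"))
  sc <- counts[counts$grouping == "smi_status" & counts$y > 0, , drop = FALSE]
  with_stage_seed(config, 4L, {
    idx <- rep(seq_len(nrow(sc)), sc$y)
    inc <- data.frame(city_id = sc$city_id[idx], area_id = sc$area_id[idx],
                      year = sc$year[idx], outcome = sc$outcome[idx],
                      smi_flag = sc$group[idx] == "SMI",
                      stringsAsFactors = FALSE)
    if (config$label_noise > 0) {
      flip <- inc$smi_flag & stats::runif(nrow(inc)) < config$label_noise
      inc$smi_flag[flip] <- FALSE
    }
    rownames(inc) <- NULL
    inc
  })
}

#' Build the end-to-end paper-like fixture bundle
#'
#' Generates every input the pipeline consumes, at the default scenario,
#' from one seed: survey microdata (N = 5493), tract profiles for 9 cities
#' x 12 tracts x 7 years, true prevalence (the true coefficients projected
#' onto the profiles), SMI-status and race count tables, an incident-level
#' table consistent with the counts, the tract-to-precinct/city mapping,
#' and a truth record of every generating parameter.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [scenario_config()].
#' @return List: `config`, `scheme`, `survey`, `profiles`, `mapping`,
#'   `prevalence_true`, `counts`, `incidents`, `truth`.
#' @export
make_paper_like_fixture <- function(seed = 1L, ...) {
  config <- scenario_config(seed = seed, ...)
  scheme <- default_coding_scheme()
  survey <- simulate_survey(config)
  profiles <- simulate_area_profiles(config)
  true_coefs <- structure(list(intercept = config$true_logit_coefs$intercept,
                               coefficients = config$true_logit_coefs$coefficients,
                               scheme = scheme),
                          class = "smi_logit")
  prevalence_true <- project_all(true_coefs, drop_profile_meta(profiles))
  counts <- simulate_event_counts(config, prevalence_true, profiles)
  incidents <- simulate_incidents(config, counts)
  mapping <- unique(profiles[c("area_id", "precinct_id", "city_id")])
  rownames(mapping) <- NULL
  truth <- list(rr_smi = config$true_rr_smi, rr_race = config$true_rr_race,
                year_effects = config$true_year_effects,
                sigma_beta = config$sigma_beta_true, phi = config$phi_true,
                base_rate = config$base_rate,
                logit_coefs = config$true_logit_coefs,
                beta_areas = attr(counts, "beta_true"))
  list(config = config, scheme = scheme, survey = survey, profiles = profiles,
       mapping = mapping, prevalence_true = prevalence_true, counts = counts,
       incidents = incidents, truth = truth)
}

# strip mapping columns so profiles match fitted design columns exactly
drop_profile_meta <- function(profiles) {
  profiles[setdiff(names(profiles), c("city_id", "precinct_id"))]
}
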