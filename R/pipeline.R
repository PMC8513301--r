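#' Run the full disparity-measurement pipeline on a synthetic scenario
#'
#' Chains every stage end to end: simulate survey/profiles/counts, apply
#' the SMI case definition, fit the individual-level logistic model,
#' project it onto the area profiles (synthetic small-area estimation),
#' replace the count table's SMI exposures with the *estimated* ones, fit
#' the requested hierarchical negative-binomial disparity models, and
#' compute city-level descriptives. All artifacts are written under
#' `out_dir` along with a manifest; on simulated data a truth-comparison
#' table joins the recovered relative risks against the generating
#' parameters.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @param models Data frame of model requests with columns `grouping`
#'   (`smi_status`/`race`) and `outcome` (`force`/`injury`); default: the
#'   SMI force and injury models plus the race force model.
#' @param mcmc MCMC settings passed to every [disparity_config()].
#' @param use_estimated_exposures Replace the generator's true SMI
#'   exposures with the pipeline's own estimates before model fitting
#'   (default `TRUE`; this is the honest end-to-end path).
#' @return Invisibly, a list with `fixture`, `fit` (the logistic fit),
#'   `prevalence_hat`, `summaries` (one `disparity_summary` per requested
#'   model, named `<grouping>_<outcome>`), `city_force`, `truth_comparison`.
#' @export
run_pipeline <- function(config, out_dir,
                         models = data.frame(
                           grouping = c("smi_status", "smi_status", "race"),
                           outcome = c("force", "injury", "force"),
                           stringsAsFactors = FALSE),
                         mcmc = list(),
                         use_estimated_exposures = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    message(line)
    warnings_log <<- c(warnings_log, line)
  }

  scheme <- default_coding_scheme()
  survey <- simulate_survey(config)
  profiles <- simulate_area_profiles(config)
  true_coefs <- structure(list(intercept = config$true_logit_coefs$intercept,
                               coefficients = config$true_logit_coefs$coefficients,
                               scheme = scheme),
                          class = "smi_logit")
  prevalence_true <- project_all(true_coefs, drop_profile_meta(profiles))
  counts_true <- simulate_event_counts(config, prevalence_true, profiles)
  fixture <- list(
    config = config, scheme = scheme, survey = survey, profiles = profiles,
    mapping = unique(profiles[c("area_id", "precinct_id", "city_id")]),
    prevalence_true = prevalence_true, counts = counts_true,
    incidents = simulate_incidents(config, counts_true),
    truth = list(rr_smi = config$true_rr_smi, rr_race = config$true_rr_race,
                 year_effects = config$true_year_effects,
                 sigma_beta = config$sigma_beta_true, phi = config$phi_true,
                 base_rate = config$base_rate,
                 logit_coefs = config$true_logit_coefs,
                 beta_areas = attr(counts_true, "beta_true")))
  write_table_csv(fixture$survey, file.path(out_dir, "survey.csv"), "survey")
  write_table_csv(fixture$counts, file.path(out_dir, "counts.csv"), "counts")

  labelled <- classify_survey(fixture$survey, fixture$scheme)
  write_table_csv(labelled, file.path(out_dir, "labelled_survey.csv"),
                  "labelled_survey")

  design <- build_design(labelled, fixture$scheme)
  fit <- fit_smi_logit(design)
  write_coefficients(fit, file.path(out_dir, "coefficients.csv"))

  prevalence_hat <- project_all(fit, drop_profile_meta(fixture$profiles))
  write_table_csv(prevalence_hat, file.path(out_dir, "prevalence.csv"),
                  "prevalence")

  counts <- fixture$counts
  if (use_estimated_exposures) {
    sel <- counts$grouping == "smi_status"
    key <- paste(counts$area_id[sel], counts$year[sel])
    pk <- paste(prevalence_hat$area_id, prevalence_hat$year)
    est <- ifelse(counts$group[sel] == "SMI",
                  prevalence_hat$n_smi[match(key, pk)],
                  prevalence_hat$n_nosmi[match(key, pk)])
    counts$exposure[sel] <- est
  }

  summaries <- list()
  for (k in seq_len(nrow(models))) {
    grouping <- models$grouping[k]
    outcome <- models$outcome[k]
    nmk <- paste(grouping, outcome, sep = "_")
    cfg <- disparity_config(grouping = grouping, outcome = outcome,
                            mcmc = utils::modifyList(list(seed = config$seed + k),
                                                     mcmc))
    dr <- withCallingHandlers(
      fit_disparity(build_model_data(counts, cfg)),
      warning = function(w) {
        note(nmk, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    sm <- summarize_disparity(dr)
    summaries[[nmk]] <- sm
    write_table_csv(as.data.frame(sm),
                    file.path(out_dir, paste0("summary_", nmk, ".csv")),
                    "summary")
    write_draws(dr, file.path(out_dir, paste0("draws_", nmk, ".csv")))
  }

  city_prev <- aggregate_profiles(drop_profile_meta(fixture$profiles),
                                  data.frame(area_id = fixture$mapping$area_id,
                                             parent_id = fixture$mapping$city_id),
                                  geography = "city")
  city_prev_hat <- project_all(fit, city_prev)
  city_force <- city_summary(fixture$incidents, city_prev_hat,
                             outcome = "force")
  utils::write.csv(city_force, file.path(out_dir, "city_summary_force.csv"),
                   row.names = FALSE)

  truth_comparison <- NULL
  tr <- fixture$truth
  rows <- list()
  for (nmk in names(summaries)) {
    sm <- summaries[[nmk]]
    g <- sm[sm$type == "group", , drop = FALSE]
    truth_vals <- if (startsWith(nmk, "smi_status")) {
      stats::setNames(tr$rr_smi, "SMI")
    } else {
      tr$rr_race[g$term]
    }
    rows[[nmk]] <- data.frame(model = nmk, term = g$term,
                              rr_hat = g$rr, ci_low = g$ci_low,
                              ci_high = g$ci_high,
                              rr_true = unname(truth_vals[g$term]),
                              covered = g$ci_low <= unname(truth_vals[g$term]) &
                                unname(truth_vals[g$term]) <= g$ci_high,
                              stringsAsFactors = FALSE)
  }
  truth_comparison <- do.call(rbind, rows)
  rownames(truth_comparison) <- NULL
  utils::write.csv(truth_comparison,
                   file.path(out_dir, "truth_comparison.csv"),
                   row.names = FALSE)

  write_manifest(file.path(out_dir, "manifest.json"), seed = config$seed,
                 config = config, warnings = warnings_log)
  invisible(list(fixture = fixture, fit = fit, prevalence_hat = prevalence_hat,
                 summaries = summaries, city_force = city_force,
                 truth_comparison = truth_comparison))
}
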