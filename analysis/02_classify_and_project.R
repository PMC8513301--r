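#!/usr/bin/env Rscript
# Stage 2: SMI classification and synthetic small-area estimation.
#
# Applies the three-criterion SMI case definition to the survey, fits the
# multivariate logistic regression of SMI on demographics, and projects
# the coefficients onto tract-, precinct-, and city-level covariate
# profiles to estimate the SMI / non-SMI population split per area-year.

suppressPackageStartupMessages(library(smidisparity))

dat <- "results/data"
out <- "results/sae"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

survey <- read_table_csv(file.path(dat, "survey.csv"), "survey")
profiles <- read_table_csv(file.path(dat, "profiles.csv"), "area_profiles")
mapping <- utils::read.csv(file.path(dat, "mapping.csv"))
scheme <- read_coding_scheme(file.path(dat, "coding_scheme.yaml"))

labelled <- classify_survey(survey, scheme)
write_table_csv(labelled, file.path(out, "labelled_survey.csv"),
                "labelled_survey")
message(sprintf("classified %d respondents: %d (%.2f%%) meet the SMI case definition",
                nrow(labelled), sum(labelled$smi), 100 * mean(labelled$smi)))

fit <- fit_smi_logit(build_design(labelled, scheme))
write_coefficients(fit, file.path(out, "coefficients.csv"))
message(sprintf("logistic fit: logLik %.1f, converged = %s",
                fit$log_likelihood, fit$converged))

tract_prof <- profiles[setdiff(names(profiles), c("city_id", "precinct_id"))]
for (level in c("tract", "precinct", "city")) {
  prof <- if (level == "tract") {
    tract_prof
  } else {
    parent <- if (level == "precinct") mapping$precinct_id else mapping$city_id
    aggregate_profiles(tract_prof,
                       data.frame(area_id = mapping$area_id, parent_id = parent),
                       geography = level)
  }
  prev <- project_all(fit, prof)
  write_table_csv(prev, file.path(out, paste0("prevalence_", level, ".csv")),
                  "prevalence")
  message(sprintf("%-8s prevalence: %d area-years, p_smi in [%.3f%%, %.3f%%]",
                  level, nrow(prev), 100 * min(prev$p_smi),
                  100 * max(prev$p_smi)))
}
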