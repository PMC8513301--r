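#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the three data sources the analysis needs — a national survey
# with SMI items (N = 5493), tract-level covariate profiles for 9 cities
# over 2011-2017, and use-of-force / injury event counts — from the full
# generative model with known parameters (SMI relative risk 11.6, Black
# 3.1, Latinx 1.0, sigma_beta 1.5, phi 1.2). Downstream stages see only
# the files written here; the truth record is kept for the final
# comparison.

suppressPackageStartupMessages(library(smidisparity))

seed <- 20L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fx <- make_paper_like_fixture(seed = seed)

write_table_csv(fx$survey, file.path(out, "survey.csv"), "survey")
write_table_csv(fx$profiles, file.path(out, "profiles.csv"), "area_profiles")
write_table_csv(fx$counts, file.path(out, "counts.csv"), "counts")
write_table_csv(fx$incidents, file.path(out, "incidents.csv"), "incidents")
utils::write.csv(fx$mapping, file.path(out, "mapping.csv"), row.names = FALSE)
write_coding_scheme(fx$scheme, file.path(out, "coding_scheme.yaml"))
truth <- fx$truth[c("rr_smi", "rr_race", "year_effects", "sigma_beta",
                    "phi", "base_rate")]
truth$rr_race <- as.list(truth$rr_race)        # keep names in JSON
truth$year_effects <- as.list(truth$year_effects)
jsonlite::write_json(truth, file.path(out, "truth.json"), auto_unbox = TRUE,
                     digits = NA)
write_manifest(file.path(out, "manifest.json"), seed = seed,
               config = fx$config)

message(sprintf("survey: %d respondents, %.2f%% with latent SMI",
                nrow(fx$survey), 100 * mean(attr(fx$survey, "latent_smi"))))
message(sprintf("profiles: %d tract-years across %d cities",
                nrow(fx$profiles), length(unique(fx$mapping$city_id))))
message(sprintf("counts: %d cells; incidents: %d force, %d injury",
                nrow(fx$counts), sum(fx$incidents$outcome == "force"),
                sum(fx$incidents$outcome == "injury")))
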