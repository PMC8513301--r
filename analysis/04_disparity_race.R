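#!/usr/bin/env Rscript
# Stage 4: the race benchmark model.
#
# Same hierarchical NB model, but with Black / Latinx / Other vs White
# groups and census race counts as exposures — the standard benchmark
# against which the SMI disparity is sized.

suppressPackageStartupMessages(library(smidisparity))

out <- "results/disparity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_table_csv("results/data/counts.csv", "counts")
truth <- jsonlite::read_json("results/data/truth.json")

sm <- suppressWarnings(fit_race_disparity(
  counts,
  disparity_config(grouping = "race", outcome = "force",
                   mcmc = list(chains = 2, iterations = 1200,
                               warmup = 600, seed = 40L))))
write_table_csv(as.data.frame(sm), file.path(out, "summary_race_force.csv"),
                "summary")
for (g in c("Black", "Latinx")) {
  row <- sm[sm$term == g, ]
  message(sprintf("force RR for %s vs White: %.2f (95%% CrI %.2f-%.2f); truth %.1f",
                  g, row$rr, row$ci_low, row$ci_high, truth$rr_race[[g]]))
}
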