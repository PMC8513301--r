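test_that("city shares are simple incident fractions", {
  inc <- data.frame(city_id = "c1", year = 2016, outcome = "force",
                    smi_flag = c(rep(TRUE, 2), rep(FALSE, 8)))
  cs <- city_shares(inc)
  expect_equal(cs$share_events_smi, 0.20)
  expect_identical(cs$n_incidents, 10L)
  inc$smi_flag <- FALSE
  expect_equal(city_shares(inc)$share_events_smi, 0)
})

test_that("a printed 28-incident table matches hand-counted shares", {
  inc <- data.frame(
    city_id = c(rep("c1", 16), rep("c2", 12)),
    year = 2016,
    outcome = c(rep("force", 12), rep("injury", 4),
                rep("force", 9), rep("injury", 3)),
    smi_flag = c(# c1 force: 3 of 12 flagged
                 TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
                 FALSE, FALSE, FALSE, FALSE,
                 # c1 injury: 2 of 4
                 TRUE, TRUE, FALSE, FALSE,
                 # c2 force: 1 of 9
                 FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 # c2 injury: 0 of 3
                 FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  force <- city_shares(inc, outcome = "force")
  expect_equal(force$share_events_smi[force$city_id == "c1"], 3 / 12)
  expect_equal(force$share_events_smi[force$city_id == "c2"], 1 / 9)
  injury <- city_shares(inc, outcome = "injury")
  expect_equal(injury$share_events_smi[injury$city_id == "c1"], 2 / 4)
  expect_equal(injury$share_events_smi[injury$city_id == "c2"], 0)
  pooled <- city_shares(inc)
  expect_equal(pooled$share_events_smi[pooled$city_id == "c1"], 5 / 16)
})

test_that("overrepresentation is share over prevalence and scale-free", {
  expect_equal(overrepresentation(0.12, 0.01), 12)
  expect_equal(overrepresentation(0.02, 0.02), 1)
  expect_error(overrepresentation(0.1, 0), "prevalence")
  # multiplying all incident counts by c leaves the ratio unchanged
  share <- 40 / 200
  share_scaled <- (40 * 5) / (200 * 5)
  expect_identical(overrepresentation(share, 0.02),
                   overrepresentation(share_scaled, 0.02))
})

test_that("paper-like share/prevalence pairs give plausible ratios", {
  # prevalences spanning 1.3-3.1% paired with shares spanning 8.7-26.8%
  prevalence <- c(0.013, 0.016, 0.019, 0.022, 0.025, 0.028, 0.031)
  ratio_truth <- c(6.7, 12.0, 6.5, 8.9, 3.5, 7.0, 8.6)
  share <- prevalence * ratio_truth
  expect_true(all(share >= 0.087 & share <= 0.268))
  ratios <- overrepresentation(share, prevalence)
  expect_equal(ratios, ratio_truth)
  expect_true(all(ratios >= 3.5 & ratios <= 13))
})

test_that("homeless adjustment follows the mediant arithmetic", {
  expect_equal(adjust_prevalence_homeless(13, 1000, 0), 0.013)
  expect_equal(adjust_prevalence_homeless(13, 1000, 100, 0.40), 53 / 1100)
  # adjusted >= unadjusted whenever the homeless SMI rate exceeds it
  p0 <- 13 / 1000
  expect_gte(adjust_prevalence_homeless(13, 1000, 50, 0.40), p0)
  expect_true(adjust_prevalence_homeless(13, 1000, 50, 0.40) <= 1)
  expect_error(adjust_prevalence_homeless(0, 0, 0), "must be > 0")
  expect_error(adjust_prevalence_homeless(1, 10, 5, 1.2), "smi_rate_homeless")
})

test_that("city_summary joins shares with prevalence and keeps latest year", {
  inc <- data.frame(
    city_id = rep(c("c1", "c2"), each = 6),
    year = rep(c(2015, 2015, 2016, 2016, 2016, 2016), 2),
    outcome = "force",
    smi_flag = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  prev <- data.frame(city_id = rep(c("c1", "c2", "c3"), each = 2),
                     year = rep(2015:2016, 3), p_smi = 0.02)
  expect_message(cs <- city_summary(inc, prev, outcome = "force"),
                 "skipping.*c3")
  expect_identical(nrow(cs), 2L)
  expect_identical(cs$year, c(2016, 2016))
  expect_equal(cs$overrepresentation, cs$share_events_smi / 0.02)
  all_years <- suppressMessages(
    city_summary(inc, prev, outcome = "force", most_recent_only = FALSE))
  expect_identical(nrow(all_years), 4L)
})

test_that("pooled and across-city share statistics are both reported", {
  st <- data.frame(city_id = c("c1", "c2"), year = 2016,
                   n_incidents = c(100, 300),
                   share_events_smi = c(0.10, 0.30),
                   prevalence_smi = 0.02,
                   overrepresentation = c(5, 15))
  ps <- pooled_share_stats(st)
  expect_equal(ps$pooled_share, (0.10 * 100 + 0.30 * 300) / 400)
  expect_equal(ps$mean_share, 0.20)
  expect_equal(ps$sd_share, stats::sd(c(0.10, 0.30)))
  expect_identical(ps$n_cities, 2L)
})
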