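test_that("summarize_disparity reproduces closed-form relative risks", {
  # constant draws: alpha = 0 -> RR 1 with a degenerate interval
  s0 <- summarize_disparity(fake_group_draws(rep(0, 400)))
  g0 <- s0[s0$type == "group", ]
  expect_equal(c(g0$rr, g0$ci_low, g0$ci_high), c(1, 1, 1))
  # constant draws at log 2 -> RR 2
  s2 <- summarize_disparity(fake_group_draws(rep(log(2), 400)))
  expect_equal(s2$rr[s2$type == "group"], 2)
  # lognormal draws: quantiles follow e^{log3 +/- 1.96 * 0.1}
  set.seed(9)
  sl <- summarize_disparity(fake_group_draws(stats::rnorm(10000, log(3), 0.1)))
  gl <- sl[sl$type == "group", ]
  expect_equal(gl$rr, 3.00, tolerance = 0.02)
  expect_equal(gl$ci_low, 3 * exp(-1.96 * 0.1), tolerance = 0.02)
  expect_equal(gl$ci_high, 3 * exp(1.96 * 0.1), tolerance = 0.02)
  expect_true(all(sl$ci_low <= sl$rr & sl$rr <= sl$ci_high))
})

test_that("split R-hat is ~1 for well-mixed draws and >1 for drifting ones", {
  set.seed(4)
  good <- stats::rnorm(2000)
  chain <- rep(1:2, each = 1000)
  expect_lt(abs(split_rhat(good, chain) - 1), 0.02)
  drifting <- c(stats::rnorm(1000), stats::rnorm(1000, 3))
  expect_gt(split_rhat(drifting, chain), 1.5)
})

test_that("the sampler recovers a known group effect on simulated counts", {
  sc <- small_count_scenario(seed = 31, true_rr = 4, sigma_beta = 0.8)
  cfg <- disparity_config(mcmc = list(chains = 2, iterations = 1000,
                                      warmup = 500, seed = 5))
  sm <- suppressWarnings(
    summarize_disparity(fit_disparity(build_model_data(sc$counts, cfg))))
  g <- sm[sm$term == "SMI", ]
  expect_gt(g$rr, 4 * 0.75)
  expect_lt(g$rr, 4 * 1.25)
  expect_true(g$ci_low <= 4 & 4 <= g$ci_high)
  expect_true(all(sm$rr[sm$type != "scale"] > 0))
})

test_that("identical seed, config, and data give identical draws", {
  sc <- small_count_scenario(seed = 32, true_rr = 2)
  cfg <- disparity_config(mcmc = list(chains = 2, iterations = 600,
                                      warmup = 300, seed = 77))
  md <- build_model_data(sc$counts, cfg)
  d1 <- suppressWarnings(fit_disparity(md))
  d2 <- suppressWarnings(fit_disparity(md))
  expect_identical(d1$draws, d2$draws)
  d3 <- suppressWarnings(fit_disparity(build_model_data(
    sc$counts, disparity_config(mcmc = list(chains = 2, iterations = 600,
                                            warmup = 300, seed = 78)))))
  expect_false(identical(d1$draws, d3$draws))
})

test_that("with no true area effects the posterior of sigma_beta collapses", {
  sc <- small_count_scenario(seed = 33, true_rr = 2, sigma_beta = 0,
                             n_cities = 12, tracts = 5)
  cfg <- disparity_config(mcmc = list(chains = 2, iterations = 1000,
                                      warmup = 500, seed = 6))
  sm <- suppressWarnings(
    summarize_disparity(fit_disparity(build_model_data(sc$counts, cfg))))
  expect_lt(sm$rr[sm$term == "sigma_beta"], 0.2)
})

test_that("swapping the reference group inverts the relative risk", {
  sc <- small_count_scenario(seed = 34, true_rr = 3)
  mc <- list(chains = 2, iterations = 1000, warmup = 500, seed = 8)
  s_fwd <- suppressWarnings(summarize_disparity(fit_disparity(build_model_data(
    sc$counts, disparity_config(mcmc = mc)))))
  s_rev <- suppressWarnings(summarize_disparity(fit_disparity(build_model_data(
    sc$counts, disparity_config(reference_group = "SMI", mcmc = mc)))))
  rr_fwd <- s_fwd$rr[s_fwd$term == "SMI"]
  rr_rev <- s_rev$rr[s_rev$term == "non_SMI"]
  expect_equal(rr_rev, 1 / rr_fwd, tolerance = 0.1)
})

test_that("race groups with identical profiles give symmetric RRs near 1", {
  g <- expand.grid(area_id = sprintf("a%d", 1:20), year = 2011:2012,
                   group = c("White", "Black", "Latinx"),
                   stringsAsFactors = FALSE)
  set.seed(12)
  base_y <- stats::rnbinom(nrow(g) / 3, mu = 40, size = 2)
  d <- data.frame(g, geography = "tract", outcome = "force",
                  y = rep(base_y, 3), exposure = 5000, stringsAsFactors = FALSE)
  sm <- suppressWarnings(fit_race_disparity(
    d, disparity_config(grouping = "race",
                        mcmc = list(chains = 2, iterations = 800,
                                    warmup = 400, seed = 3))))
  rr <- sm$rr[sm$type == "group"]
  expect_true(all(abs(rr - 1) < 0.1))
  expect_identical(attr(sm, "reference_group"), "White")
})

test_that("fewer than two areas is rejected", {
  d <- data.frame(area_id = "a1", geography = "tract", year = 2011:2012,
                  group = rep(c("non_SMI", "SMI"), each = 2), outcome = "force",
                  y = 1:4, exposure = 100, stringsAsFactors = FALSE)
  expect_error(fit_disparity(build_model_data(d, disparity_config())),
               ">= 2 areas")
})
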