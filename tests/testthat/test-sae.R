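sim_logit_data <- function(n, beta0, betas, seed) {
  set.seed(seed)
  X <- cbind(x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1, 0.4),
             x3 = stats::runif(n))
  y <- stats::rbinom(n, 1, stats::plogis(beta0 + drop(X %*% betas)))
  list(X = X, y = y)
}

test_that("fit_smi_logit matches the independent quasi-Newton MLE oracle", {
  d <- sim_logit_data(2000, -1, c(0.5, -0.3, 0.8), seed = 11)
  fit <- fit_smi_logit(d$X, d$y)
  oracle <- logit_mle_oracle(d$X, d$y)
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - oracle)), 1e-6)
  expect_true(fit$converged)
  # log-likelihood at the optimum agrees with a direct evaluation
  eta <- oracle[1] + drop(d$X %*% oracle[-1])
  expect_equal(fit$log_likelihood, sum(d$y * eta - log1p(exp(eta))),
               tolerance = 1e-8)
})

test_that("fitted coefficients recover the truth at n = 5000", {
  truth <- c(-1, 0.5, -0.3, 0.8)
  d <- sim_logit_data(5000, truth[1], truth[-1], seed = 7)
  fit <- fit_smi_logit(d$X, d$y)
  # tolerance ~ 2-3 asymptotic SEs at this n and case rate
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - truth)), 0.15)
})

test_that("a null covariate's coefficient estimates near zero", {
  set.seed(3)
  n <- 4000
  X <- cbind(signal = stats::rnorm(n), noise = stats::rnorm(n))
  y <- stats::rbinom(n, 1, stats::plogis(-0.5 + X[, "signal"]))
  fit <- fit_smi_logit(X, y)
  expect_lt(abs(fit$coefficients["noise"]), 0.25)  # ~3 SEs at n = 4000
})

test_that("degenerate fits are rejected with informative errors", {
  expect_error(fit_smi_logit(cbind(x = 1:5), rep(1, 5)),
               "at least one case and one non-case")
  X <- cbind(a = c(1, 0, 1, 0, 1, 1), b = c(2, 0, 2, 0, 2, 2))  # b = 2a
  expect_error(fit_smi_logit(X, c(1, 0, 1, 0, 0, 1)), "collinear.*b")
})

test_that("weighted fits reproduce replication of rows", {
  d <- sim_logit_data(400, -0.5, c(0.7, 0.2, -0.4), seed = 21)
  w <- sample(1:3, 400, replace = TRUE)
  fit_w <- fit_smi_logit(d$X, d$y, weights = w)
  idx <- rep(seq_len(400), w)
  fit_r <- fit_smi_logit(d$X[idx, ], d$y[idx])
  expect_equal(c(fit_w$intercept, fit_w$coefficients),
               c(fit_r$intercept, fit_r$coefficients), tolerance = 1e-6)
})

test_that("projection converts logits to prevalence and exposure counts", {
  coefs <- structure(list(intercept = 0,
                          coefficients = c(a = 0, b = 0)), class = "smi_logit")
  prof <- data.frame(area_id = "t1", geography = "tract", year = 2015,
                     adult_population = 1000, a = 0.4, b = 2.2)
  est <- project_prevalence(coefs, prof)
  expect_identical(est$p_smi, 0.5)  # logit 0 exactly
  expect_identical(est$n_smi + est$n_nosmi, 1000)

  coefs$intercept <- -4.33
  est <- project_prevalence(coefs, prof)
  expect_equal(est$p_smi, 0.0130, tolerance = 2e-3)
  expect_equal(est$n_smi, 13.0, tolerance = 2e-3)

  bad <- prof; names(bad)[names(bad) == "b"] <- "zz"
  expect_error(project_prevalence(coefs, bad), "missing: \\{b\\}.*unexpected: \\{zz\\}")
})

test_that("project_all preserves order, propagates context, and normalizes", {
  fx <- get_fixture()
  lab <- classify_survey(fx$survey, fx$scheme)
  fit <- fit_smi_logit(build_design(lab, fx$scheme))
  prof <- fx$profiles[setdiff(names(fx$profiles), c("city_id", "precinct_id"))]
  est <- project_all(fit, prof)
  expect_identical(nrow(est), nrow(prof))
  expect_identical(est$area_id, prof$area_id)
  # normalization to relative error 1e-9
  expect_lt(max(abs(est$n_smi + est$n_nosmi - est$adult_population) /
                  pmax(est$adult_population, 1)), 1e-9)
  expect_equal(sum(est$n_smi), sum(est$p_smi * est$adult_population))
  expect_identical(nrow(project_all(fit, prof[0, ])), 0L)
})

test_that("p_smi is strictly monotone in a positively weighted covariate", {
  coefs <- structure(list(intercept = -3,
                          coefficients = c(a = 1.2, b = -0.5)),
                     class = "smi_logit")
  prof <- data.frame(area_id = "t", geography = "tract", year = 2011,
                     adult_population = 100, a = 0.2, b = 0.3)
  p0 <- project_prevalence(coefs, prof)$p_smi
  prof$a <- 0.5
  expect_gt(project_prevalence(coefs, prof)$p_smi, p0)
})

test_that("projection onto the microdata's own covariate means is the plug-in rate", {
  fx <- get_fixture()
  lab <- classify_survey(fx$survey, fx$scheme)
  des <- build_design(lab, fx$scheme)
  fit <- fit_smi_logit(des)
  prof <- data.frame(area_id = "pool", geography = "city", year = 2011,
                     adult_population = 1, stringsAsFactors = FALSE)
  for (cn in colnames(des$X)) prof[[cn]] <- mean(des$X[, cn])
  est <- project_prevalence(fit, prof)
  direct <- stats::plogis(fit$intercept +
                            sum(fit$coefficients * colMeans(des$X)))
  expect_equal(est$p_smi, direct, tolerance = 1e-12)
  # the plug-in sits near (slightly below, by logit convexity at low
  # prevalence) the observed microdata rate
  expect_lt(abs(est$p_smi - mean(lab$smi)), 0.01)
  expect_lte(est$p_smi, mean(lab$smi))
})

test_that("precinct profiles are population-weighted tract averages", {
  prof <- data.frame(area_id = c("t1", "t2"), geography = "tract",
                     year = 2011, adult_population = c(1000, 3000),
                     a = c(0.2, 0.6), stringsAsFactors = FALSE)
  agg <- aggregate_profiles(prof, data.frame(area_id = c("t1", "t2"),
                                             parent_id = "p1"))
  expect_identical(agg$adult_population, 4000)
  expect_equal(agg$a, (0.2 * 1000 + 0.6 * 3000) / 4000)
  expect_identical(agg$geography, "precinct")
})
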