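#' Configuration for the hierarchical negative-binomial disparity model
#'
#' @param grouping `"smi_status"` (groups `non_SMI` reference, `SMI`) or
#'   `"race"` (reference `White`).
#' @param outcome `"force"` or `"injury"`.
#' @param reference_group Reference level absorbed into the intercept;
#'   defaults to `non_SMI` / `White` by grouping.
#' @param reference_year Reference year; `NULL` (default) means the
#'   earliest year present in the data.
#' @param priors List: `fixed_effects_sd` (normal SD on the intercept,
#'   group, and year effects; default 5), `sigma_beta_scale` and
#'   `sigma_beta_df` (half-Student-t scale/df on the area-effect SD;
#'   defaults 2.5 and 3), `phi_shape`, `phi_rate` (gamma prior on the
#'   dispersion; defaults 0.01, 0.01). Weakly informative throughout.
#' @param mcmc List: `chains` (>= 2, default 4), `iterations` (total per
#'   chain, default 2000), `warmup` (adaptation + burn-in, default 1000),
#'   `seed` (default 1).
#' @param point `"median"` (default) or `"mean"` posterior point estimate
#'   for relative risks.
#' @param exposure_floor Optional positive floor applied to exposures
#'   instead of dropping zero-exposure cells (`NULL`, the default, drops).
#' @return A list of class `disparity_config`.
#' @export
disparity_config <- function(grouping = c("smi_status", "race"),
                             outcome = c("force", "injury"),
                             reference_group = NULL,
                             reference_year = NULL,
                             priors = list(),
                             mcmc = list(),
                             point = c("median", "mean"),
                             exposure_floor = NULL) {
  grouping <- match.arg(grouping)
  outcome <- match.arg(outcome)
  if (is.null(reference_group)) {
    reference_group <- if (grouping == "smi_status") "non_SMI" else "White"
  }
  pr <- utils::modifyList(list(fixed_effects_sd = 5, sigma_beta_scale = 2.5,
                               sigma_beta_df = 3, phi_shape = 0.01,
                               phi_rate = 0.01), priors)
  mc <- utils::modifyList(list(chains = 4L, iterations = 2000L,
                               warmup = 1000L, seed = 1L), mcmc)
  if (mc$chains < 2L) stop("mcmc$chains must be >= 2", call. = FALSE)
  if (!(mc$iterations > mc$warmup && mc$warmup > 0L)) {
    stop("need mcmc$iterations > mcmc$warmup > 0", call. = FALSE)
  }
  structure(list(grouping = grouping, outcome = outcome,
                 reference_group = reference_group,
                 reference_year = reference_year,
                 priors = pr, mcmc = mc, point = match.arg(point),
                 exposure_floor = exposure_floor),
            class = "disparity_config")
}

#' Assemble model arrays from event counts
#'
#' Filters the count table to the configured grouping and outcome, drops
#' (or floors) non-positive exposures, and builds the arrays the sampler
#' consumes: the count vector, the log-exposure offset, indicator columns
#' for non-reference groups and years, and an area index. The reference
#' group and reference year are absorbed into the intercept.
#'
#' @param counts Data frame with columns `area_id`, `geography`, `year`,
#'   `group`, `outcome`, `y`, `exposure`.
#' @param config A [disparity_config()].
#' @return List: `y`, `log_exposure`, `group_x` (n x G indicator matrix),
#'   `year_x` (n x T-1 indicator matrix), `area` (integer index),
#'   `area_levels`, `group_levels`, `year_levels` (non-reference, in
#'   order), `reference_group`, `reference_year`, `n_dropped`, `config`.
#' @export
build_model_data <- function(counts, config) {
  stopifnot(inherits(config, "disparity_config"))
  needed <- c("area_id", "year", "group", "outcome", "y", "exposure")
  missing <- setdiff(needed, names(counts))
  if (length(missing)) {
    stop("counts missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- counts
  if ("grouping" %in% names(d)) d <- d[d$grouping == config$grouping, , drop = FALSE]
  d <- d[d$outcome == config$outcome, , drop = FALSE]
  if (nrow(d) == 0L) {
    stop(sprintf("no rows with outcome '%s'", config$outcome), call. = FALSE)
  }
  if (any(d$y < 0) || any(d$y != floor(d$y))) {
    stop("counts `y` must be non-negative integers", call. = FALSE)
  }
  n_dropped <- 0L
  bad <- d$exposure <= 0
  if (any(bad)) {
    if (is.null(config$exposure_floor)) {
      n_dropped <- sum(bad)
      warning(sprintf("dropped %d cell(s) with non-positive exposure", n_dropped),
              call. = FALSE)
      d <- d[!bad, , drop = FALSE]
    } else {
      d$exposure[bad] <- config$exposure_floor
    }
  }
  if (nrow(d) == 0L) stop("all cells dropped: no positive exposures", call. = FALSE)

  groups <- unique(d$group)
  if (!config$reference_group %in% groups) {
    stop(sprintf("reference group '%s' not present in data", config$reference_group),
         call. = FALSE)
  }
  group_levels <- setdiff(sort(groups), config$reference_group)
  ref_year <- if (is.null(config$reference_year)) min(d$year) else config$reference_year
  if (!ref_year %in% d$year) {
    stop(sprintf("reference year %s not present in data", ref_year), call. = FALSE)
  }
  year_levels <- setdiff(sort(unique(d$year)), ref_year)
  area_levels <- sort(unique(d$area_id))

  group_x <- vapply(group_levels, function(g) as.numeric(d$group == g),
                    numeric(nrow(d)))
  year_x <- vapply(year_levels, function(t) as.numeric(d$year == t),
                   numeric(nrow(d)))
  dim(group_x) <- c(nrow(d), length(group_levels))
  dim(year_x) <- c(nrow(d), length(year_levels))
  colnames(group_x) <- group_levels
  colnames(year_x) <- as.character(year_levels)

  list(y = as.integer(d$y),
       log_exposure = log(d$exposure),
       group_x = group_x, year_x = year_x,
       area = match(d$area_id, area_levels),
       area_levels = area_levels,
       group_levels = group_levels,
       year_levels = year_levels,
       reference_group = config$reference_group,
       reference_year = ref_year,
       n_dropped = n_dropped,
       config = config)
}

nb_model_string <- function(has_years) {
  paste0("
model {
  for (n in 1:N) {
    y[n] ~ dnegbin(pnb[n], phi)
    pnb[n] <- phi / (phi + mu[n])
    log(mu[n]) <- log_expo[n] + u + inprod(Xg[n, ], alpha)",
    if (has_years) " + inprod(Xt[n, ], delta)" else "", " + beta[area[n]]
  }
  u ~ dnorm(0, fe_prec)
  for (g in 1:G) { alpha[g] ~ dnorm(0, fe_prec) }
",
    if (has_years) "  for (t in 1:T) { delta[t] ~ dnorm(0, fe_prec) }\n" else "", "
  for (i in 1:A) { z[i] ~ dnorm(0, 1); beta[i] <- sigma_beta * z[i] }
  sigma_beta ~ dt(0, sb_prec, sb_df) T(0,)
  phi ~ dgamma(phi_shape, phi_rate)
}")
}

#' Fit the hierarchical negative-binomial disparity model
#'
#' Bayesian fit of the exposure-offset count model
#' \deqn{y_{gti} \sim \mathrm{NB}(n_{gti}\, e^{u + \alpha_g + \delta_t +
#' \beta_i},\ \phi), \qquad \beta_i \sim \mathrm{Normal}(0, \sigma_\beta^2)}
#' where \eqn{n_{gti}} is the group's population exposure (entering as a
#' log offset), \eqn{\alpha_g} are group effects (relative risks on the
#' exponential scale), \eqn{\delta_t} year effects, and \eqn{\beta_i}
#' area random effects with a non-centered parameterization. Weakly
#' informative priors throughout (see [disparity_config()]). Sampling runs
#' in JAGS; given the same data, configuration, and seed the draws are
#' reproducible.
#'
#' @param model_data Arrays from [build_model_data()], or a raw count table
#'   (in which case `config` is required and [build_model_data()] is called).
#' @param config A [disparity_config()]; defaults to the one carried in
#'   `model_data`.
#' @return An object of class `posterior_draws`: `draws` (matrix, one row
#'   per retained draw, columns `u`, `alpha_<group>`, `delta_<year>`,
#'   `sigma_beta`, `phi`, plus `beta_<area>`), `chain` and `draw` indices,
#'   `model_data`, and `config`. If any reported parameter has split R-hat
#'   above 1.05 a `convergence_flag` attribute is set (with a warning).
#' @export
fit_disparity <- function(model_data, config = NULL) {
  if (is.data.frame(model_data)) {
    if (is.null(config)) stop("config required with a raw count table", call. = FALSE)
    model_data <- build_model_data(model_data, config)
  }
  if (is.null(config)) config <- model_data$config
  stopifnot(inherits(config, "disparity_config"))
  md <- model_data
  A <- length(md$area_levels)
  if (A < 2L) stop("need >= 2 areas to identify sigma_beta", call. = FALSE)
  G <- length(md$group_levels)
  Tn <- length(md$year_levels)
  has_years <- Tn > 0L

  jd <- list(y = md$y, log_expo = md$log_exposure, Xg = md$group_x,
             area = md$area, N = length(md$y), G = G, A = A,
             fe_prec = 1 / config$priors$fixed_effects_sd^2,
             sb_prec = 1 / config$priors$sigma_beta_scale^2,
             sb_df = config$priors$sigma_beta_df,
             phi_shape = config$priors$phi_shape,
             phi_rate = config$priors$phi_rate)
  if (has_years) { jd$Xt <- md$year_x; jd$T <- Tn }

  mc <- config$mcmc
  inits <- lapply(seq_len(mc$chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (mc$seed * 1000L + k) %% 2147483647L)
  })
  n_adapt <- max(200L, floor(mc$warmup / 2))
  n_burn <- mc$warmup - n_adapt
  jm <- tryCatch(
    rjags::jags.model(textConnection(nb_model_string(has_years)), data = jd,
                      inits = inits, n.chains = mc$chains,
                      n.adapt = n_adapt, quiet = TRUE),
    error = function(e) stop("JAGS model initialization failed: ",
                             conditionMessage(e), call. = FALSE))
  if (n_burn > 0) stats::update(jm, n_burn, progress.bar = "none")
  monitors <- c("u", "alpha", if (has_years) "delta", "sigma_beta", "phi", "beta")
  samp <- rjags::coda.samples(jm, monitors, n.iter = mc$iterations - mc$warmup,
                              progress.bar = "none")

  rename <- function(nms) {
    out <- nms
    for (g in seq_len(G)) {
      out[out == if (G == 1) "alpha" else sprintf("alpha[%d]", g)] <-
        paste0("alpha_", md$group_levels[g])
    }
    if (has_years) for (t in seq_len(Tn)) {
      out[out == if (Tn == 1) "delta" else sprintf("delta[%d]", t)] <-
        paste0("delta_", md$year_levels[t])
    }
    for (i in seq_len(A)) {
      out[out == if (A == 1) "beta" else sprintf("beta[%d]", i)] <-
        paste0("beta_", md$area_levels[i])
    }
    out
  }
  per_chain <- lapply(samp, function(m) {
    m <- as.matrix(m)
    colnames(m) <- rename(colnames(m))
    m
  })
  draws <- do.call(rbind, per_chain)
  n_iter <- nrow(per_chain[[1L]])
  obj <- structure(list(draws = draws,
                        chain = rep(seq_len(mc$chains), each = n_iter),
                        draw = rep(seq_len(n_iter), times = mc$chains),
                        model_data = md, config = config),
                   class = "posterior_draws")
  core <- c("u", paste0("alpha_", md$group_levels),
            if (has_years) paste0("delta_", md$year_levels),
            "sigma_beta", "phi")
  rh <- vapply(core, function(p) split_rhat(draws[, p], obj$chain), 0)
  if (any(rh > 1.05, na.rm = TRUE)) {
    attr(obj, "convergence_flag") <- TRUE
    warning("split R-hat > 1.05 for: ",
            paste(core[rh > 1.05], collapse = ", "),
            "; increase iterations", call. = FALSE)
  }
  obj
}

#' Split R-hat (potential scale reduction) for one parameter
#'
#' Each chain is split in half and the standard between/within-variance
#' scale-reduction statistic is computed over the resulting half-chains.
#'
#' @param x Numeric vector of draws, stacked by chain.
#' @param chain Integer chain index, same length as `x`.
#' @return The split R-hat statistic (>= 1 up to sampling noise; `NA` for
#'   a constant parameter).
#' @export
split_rhat <- function(x, chain) {
  halves <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    h <- length(v) %/% 2L
    if (h < 2L) return(NA_real_)
    halves <- c(halves, list(v[seq_len(h)], v[(length(v) - h + 1L):length(v)]))
  }
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize posterior draws into relative risks
#'
#' For every group and year effect the relative risk is the posterior
#' point estimate (median by default) of `exp(coefficient)` with an
#' equal-tailed 95% credible interval (2.5th/97.5th percentiles of the
#' exponentiated draws). Posterior medians of `sigma_beta` and `phi`, and
#' split R-hat / effective sample size per parameter, are attached.
#'
#' @param draws A `posterior_draws` object from [fit_disparity()].
#' @return Data frame of class `disparity_summary`: `term`, `type`
#'   (`group`/`year`/`scale`), `rr` (for `scale` rows, the posterior
#'   median on the natural scale), `ci_low`, `ci_high`, `rhat`, `ess`.
#' @export
summarize_disparity <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  md <- draws$model_data
  dm <- draws$draws
  if (nrow(dm) == 0L) stop("no posterior draws", call. = FALSE)
  point_fun <- if (draws$config$point == "mean") mean else stats::median
  ess <- function(p) {
    ml <- coda::as.mcmc.list(lapply(split(dm[, p], draws$chain), coda::as.mcmc))
    unname(coda::effectiveSize(ml))
  }
  row_for <- function(p, type, exponentiate) {
    v <- dm[, p]
    vv <- if (exponentiate) exp(v) else v
    data.frame(term = sub("^(alpha|delta)_", "", p), type = type,
               rr = point_fun(vv),
               ci_low = unname(stats::quantile(vv, 0.025)),
               ci_high = unname(stats::quantile(vv, 0.975)),
               rhat = split_rhat(v, draws$chain), ess = ess(p),
               stringsAsFactors = FALSE)
  }
  group_params <- if (length(md$group_levels)) {
    paste0("alpha_", md$group_levels)
  } else {
    character()
  }
  year_params <- if (length(md$year_levels)) {
    paste0("delta_", md$year_levels)
  } else {
    character()
  }
  rows <- c(
    lapply(group_params, row_for, type = "group", exponentiate = TRUE),
    lapply(year_params, row_for, type = "year", exponentiate = TRUE),
    lapply(c("sigma_beta", "phi"), row_for, type = "scale",
           exponentiate = FALSE)
  )
  out <- do.call(rbind, rows)
  out$term[out$type == "scale"] <- c("sigma_beta", "phi")
  attr(out, "reference_group") <- md$reference_group
  attr(out, "reference_year") <- md$reference_year
  attr(out, "n_cells") <- length(md$y)
  attr(out, "convergence_flag") <- isTRUE(attr(draws, "convergence_flag"))
  class(out) <- c("disparity_summary", "data.frame")
  out
}

#' @export
print.disparity_summary <- function(x, ...) {
  cat(sprintf("Disparity model summary (reference group '%s', reference year %s, %d cells)\n",
              attr(x, "reference_group"), attr(x, "reference_year"),
              attr(x, "n_cells")))
  df <- as.data.frame(x)
  df[c("rr", "ci_low", "ci_high", "rhat")] <-
    lapply(df[c("rr", "ci_low", "ci_high", "rhat")], round, 3)
  df$ess <- round(df$ess)
  print(df, row.names = FALSE)
  if (isTRUE(attr(x, "convergence_flag"))) {
    cat("Warning: split R-hat > 1.05 on at least one parameter\n")
  }
  invisible(x)
}

#' Fit and summarize the race-disparity model
#'
#' Same hierarchical negative-binomial model as [fit_disparity()], with
#' race groups (reference `White`) and ACS race population counts as
#' exposures; reports relative risks for Black and Latinx (and any other
#' non-reference groups present).
#'
#' @param counts Event-count table with race groups in `group`.
#' @param config A [disparity_config()]; `grouping` is forced to `"race"`.
#' @return A `disparity_summary`.
#' @export
fit_race_disparity <- function(counts, config = disparity_config(grouping = "race")) {
  cfg <- config
  cfg$grouping <- "race"
  if (cfg$reference_group == "non_SMI") cfg$reference_group <- "White"
  summarize_disparity(fit_disparity(build_model_data(counts, cfg)))
}
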