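#' Fit the individual-level logistic regression of SMI on demographics
#'
#' Unpenalized (optionally weighted) maximum-likelihood logistic regression,
#' fit by iteratively reweighted least squares with a convergence tolerance
#' of 1e-8 on the relative deviance change and at most 100 iterations. The
#' fitted coefficients are the inputs to the synthetic small-area
#' projection ([project_prevalence()]).
#'
#' @param design A design list from [build_design()] (`X`, `y`, `weights`,
#'   `scheme`), or a bare numeric matrix.
#' @param response 0/1 response vector; taken from `design$y` when `design`
#'   is a [build_design()] list.
#' @param weights Positive case weights; default all 1.
#' @param scheme Coding scheme reference carried into the result; taken
#'   from the design list when available.
#' @return An object of class `smi_logit`: `intercept`, `coefficients`
#'   (named, in design-column order), `log_likelihood`, `converged`, `n`,
#'   and `scheme`.
#' @export
fit_smi_logit <- function(design, response = NULL, weights = NULL, scheme = NULL) {
  if (is.list(design) && !is.null(design$X)) {
    X <- design$X
    response <- if (is.null(response)) design$y else response
    weights <- if (is.null(weights)) design$weights else weights
    scheme <- if (is.null(scheme)) design$scheme else scheme
  } else {
    X <- design
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("design matrix must have column names", call. = FALSE)
  y <- as.numeric(response)
  if (length(y) != nrow(X)) stop("response length does not match design rows", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("response must be 0/1", call. = FALSE)
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("need at least one case and one non-case", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(y))

  Xi <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qx$pivot[(qx$rank + 1L):ncol(Xi)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  fit <- stats::glm.fit(Xi, y, weights = weights,
                        family = stats::binomial(),
                        control = list(epsilon = 1e-8, maxit = 100))
  cf <- fit$coefficients
  if (!fit$converged) {
    stop(sprintf(paste0("logistic fit did not converge in 100 IRLS iterations ",
                        "(largest |coefficient| %.2f on '%s'); possible separation"),
                 max(abs(cf)), names(cf)[which.max(abs(cf))]), call. = FALSE)
  }
  if (fit$boundary || max(abs(cf[-1])) > 15) {
    warning(sprintf("fit at boundary or extreme coefficient (max |coef| %.2f); possible quasi-separation",
                    max(abs(cf))), call. = FALSE)
  }
  eta <- drop(Xi %*% cf)
  ll <- sum(weights * (y * eta - log1p(exp(eta))))
  structure(list(intercept = unname(cf[1L]),
                 coefficients = cf[-1L],
                 log_likelihood = ll,
                 converged = fit$converged,
                 n = length(y),
                 scheme = scheme),
            class = "smi_logit")
}

#' @export
print.smi_logit <- function(x, ...) {
  cat(sprintf("Logistic SMI model: n = %d, logLik = %.3f, converged = %s\n",
              x$n, x$log_likelihood, x$converged))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

check_profile_invariants <- function(profiles) {
  needed <- c("area_id", "geography", "year", "adult_population")
  missing <- setdiff(needed, names(profiles))
  if (length(missing)) {
    stop("area profiles missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(profiles$adult_population < 0)) {
    stop("adult_population must be >= 0", call. = FALSE)
  }
  invisible(profiles)
}

#' Project fitted SMI coefficients onto one area covariate profile
#'
#' The synthetic small-area estimator: the area's aggregate covariate
#' summaries (indicator proportions and continuous means) are plugged into
#' the individual-level linear predictor, the resulting logit is converted
#' to a probability, and that probability is multiplied by the adult
#' population to split the area into SMI and non-SMI exposure counts.
#'
#' @param coefs An `smi_logit` fit (or a list with `intercept` and named
#'   `coefficients`).
#' @param profile A one-row data frame (or named list) with `area_id`,
#'   `geography`, `year`, `adult_population`, and one column per design
#'   column of the fit.
#' @return One-row data frame: `area_id`, `geography`, `year`,
#'   `adult_population`, `p_smi`, `n_smi`, `n_nosmi`. By construction
#'   `n_smi + n_nosmi == adult_population` and `n_smi == p_smi *
#'   adult_population`.
#' @export
project_prevalence <- function(coefs, profile) {
  profile <- as.data.frame(profile, stringsAsFactors = FALSE)
  stopifnot(nrow(profile) == 1L)
  check_profile_invariants(profile)
  want <- names(coefs$coefficients)
  have <- setdiff(names(profile),
                  c("area_id", "geography", "year", "adult_population",
                    "city_id", "precinct_id"))
  extra <- setdiff(have, want)
  missing <- setdiff(want, have)
  if (length(extra) || length(missing)) {
    stop("profile columns do not match fitted coefficients; missing: {",
         paste(missing, collapse = ", "), "}, unexpected: {",
         paste(extra, collapse = ", "), "}", call. = FALSE)
  }
  x <- as.numeric(profile[1L, want])
  logit <- coefs$intercept + sum(coefs$coefficients * x)
  p <- stats::plogis(logit)
  pop <- profile$adult_population
  data.frame(area_id = profile$area_id, geography = profile$geography,
             year = profile$year, adult_population = pop,
             p_smi = p, n_smi = p * pop, n_nosmi = (1 - p) * pop,
             stringsAsFactors = FALSE)
}

#' Project fitted SMI coefficients onto a table of area profiles
#'
#' @inheritParams project_prevalence
#' @param profiles Data frame of area profiles, one row per area-year.
#' @return Data frame of prevalence estimates, one row per profile, order
#'   preserved.
#' @export
project_all <- function(coefs, profiles) {
  check_profile_invariants(profiles)
  if (nrow(profiles) == 0L) {
    return(data.frame(area_id = character(), geography = character(),
                      year = integer(), adult_population = numeric(),
                      p_smi = numeric(), n_smi = numeric(),
                      n_nosmi = numeric(), stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    tryCatch(project_prevalence(coefs, profiles[i, , drop = FALSE]),
             error = function(e) {
               stop(sprintf("area '%s' (row %d): %s",
                            profiles$area_id[i], i, conditionMessage(e)),
                    call. = FALSE)
             })
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate tract profiles to a coarser geography
#'
#' Builds precinct- or city-level covariate profiles as population-weighted
#' averages of their member tracts (weights = tract adult population);
#' adult populations sum. Used when profiles are only available at the
#' tract level.
#'
#' @param profiles Tract-level area profiles.
#' @param mapping Data frame with columns `area_id` (tract) and `parent_id`.
#' @param geography Geography label for the output (e.g. `"precinct"`).
#' @return Data frame of aggregated profiles, one row per parent-year.
#' @export
aggregate_profiles <- function(profiles, mapping, geography = "precinct") {
  check_profile_invariants(profiles)
  if (!all(c("area_id", "parent_id") %in% names(mapping))) {
    stop("mapping needs columns `area_id` and `parent_id`", call. = FALSE)
  }
  unmapped <- setdiff(profiles$area_id, mapping$area_id)
  if (length(unmapped)) {
    stop("tract(s) missing from mapping: ", paste(unmapped[1:3], collapse = ", "),
         call. = FALSE)
  }
  parent <- mapping$parent_id[match(profiles$area_id, mapping$area_id)]
  meta <- c("area_id", "geography", "year", "adult_population")
  design_cols <- setdiff(names(profiles), c(meta, "city_id", "precinct_id"))
  pieces <- split(seq_len(nrow(profiles)),
                  list(parent = parent, year = profiles$year), drop = TRUE)
  out <- lapply(pieces, function(idx) {
    w <- profiles$adult_population[idx]
    pop <- sum(w)
    sums <- if (pop > 0) {
      vapply(design_cols, function(cl) sum(w * profiles[[cl]][idx]) / pop, 0)
    } else {
      vapply(design_cols, function(cl) mean(profiles[[cl]][idx]), 0)
    }
    row <- data.frame(area_id = parent[idx[1L]], geography = geography,
                      year = profiles$year[idx[1L]], adult_population = pop,
                      stringsAsFactors = FALSE)
    for (cl in design_cols) row[[cl]] <- sums[[cl]]
    row
  })
  res <- do.call(rbind, out)
  res <- res[order(res$area_id, res$year), , drop = FALSE]
  rownames(res) <- NULL
  res
}
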