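table_schemas <- function() {
  list(
    survey = c("respondent_id", "days_unable_to_function", "imp_work",
               "imp_home", "imp_relationships", "imp_social",
               "disorder_duration_months"),
    labelled_survey = c("respondent_id", "smi", "weight"),
    area_profiles = c("area_id", "geography", "year", "adult_population"),
    coefficients = c("term", "estimate"),
    prevalence = c("area_id", "geography", "year", "adult_population",
                   "p_smi", "n_smi", "n_nosmi"),
    counts = c("area_id", "geography", "year", "group", "outcome", "y",
               "exposure"),
    incidents = c("city_id", "year", "outcome", "smi_flag"),
    draws = c("chain", "draw", "parameter", "value"),
    summary = c("term", "type", "rr", "ci_low", "ci_high", "rhat", "ess")
  )
}

#' Read a pipeline table from CSV
#'
#' Thin schema-validated reader over the plain-CSV dialect every pipeline
#' stage shares. Tolerant of CRLF line endings; a missing required column
#' is an error naming the column and the file.
#'
#' @param path CSV file path.
#' @param what Table kind: one of `"survey"`, `"labelled_survey"`,
#'   `"area_profiles"`, `"coefficients"`, `"prevalence"`, `"counts"`,
#'   `"incidents"`, `"draws"`, `"summary"`.
#' @return Data frame.
#' @export
read_table_csv <- function(path, what) {
  schemas <- table_schemas()
  what <- match.arg(what, names(schemas))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- schemas[[what]]
  if (what == "survey") {
    required <- c(required, paste0("diag_", smi_diagnosis_catalogue()))
  }
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop(sprintf("%s file '%s' is missing column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (what == "survey" && !"weight" %in% names(d)) d$weight <- 1
  if (what %in% c("labelled_survey", "incidents")) {
    flag <- if (what == "incidents") "smi_flag" else "smi"
    d[[flag]] <- as.logical(d[[flag]]) | d[[flag]] == 1
  }
  d
}

#' Write a pipeline table to CSV
#'
#' @param x Data frame.
#' @param path Output path; parent directories are created.
#' @param what Table kind (see [read_table_csv()]); validated before
#'   writing so that write-then-read is the identity on valid tables.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path, what) {
  schemas <- table_schemas()
  what <- match.arg(what, names(schemas))
  missing <- setdiff(schemas[[what]], names(x))
  if (length(missing)) {
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  x <- as.data.frame(x)
  for (cl in names(x)) if (is.logical(x[[cl]])) x[[cl]] <- as.integer(x[[cl]])
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Export fitted logistic coefficients
#'
#' Two-column CSV (`term`, `estimate`, intercept first) plus a JSON
#' sidecar with the log-likelihood, sample size, and convergence flag.
#'
#' @param fit An `smi_logit` from [fit_smi_logit()].
#' @param path Output CSV path; the sidecar is `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(fit, path) {
  stopifnot(inherits(fit, "smi_logit"))
  df <- data.frame(term = c("(Intercept)", names(fit$coefficients)),
                   estimate = c(fit$intercept, unname(fit$coefficients)))
  write_table_csv(df, path, "coefficients")
  jsonlite::write_json(list(log_likelihood = fit$log_likelihood, n = fit$n,
                            converged = fit$converged),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read logistic coefficients written by [write_coefficients()]
#' @param path CSV path.
#' @return An `smi_logit`-shaped list usable by [project_all()].
#' @export
read_coefficients <- function(path) {
  d <- read_table_csv(path, "coefficients")
  int <- d$estimate[d$term == "(Intercept)"]
  if (!length(int)) stop("coefficient file has no (Intercept) row", call. = FALSE)
  rest <- d[d$term != "(Intercept)", ]
  structure(list(intercept = int,
                 coefficients = stats::setNames(rest$estimate, rest$term),
                 log_likelihood = NA_real_, converged = NA, n = NA_integer_,
                 scheme = NULL),
            class = "smi_logit")
}

#' Export posterior draws in long format
#'
#' @param draws A `posterior_draws` from [fit_disparity()].
#' @param path Output CSV path.
#' @param include_areas Include the per-area `beta_*` parameters (default
#'   `FALSE`; they dominate file size).
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path, include_areas = FALSE) {
  stopifnot(inherits(draws, "posterior_draws"))
  keep <- colnames(draws$draws)
  if (!include_areas) keep <- keep[!startsWith(keep, "beta_")]
  long <- do.call(rbind, lapply(keep, function(p) {
    data.frame(chain = draws$chain, draw = draws$draw, parameter = p,
               value = draws$draws[, p], stringsAsFactors = FALSE)
  }))
  write_table_csv(long, path, "draws")
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline run: the seed, the
#' scenario/model configuration, package and JAGS versions, and any
#' warnings accumulated along the way.
#'
#' @param path Output JSON path.
#' @param seed Master seed of the run.
#' @param config Configuration list (coerced to JSON).
#' @param warnings Character vector of machine-readable warnings.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, config, warnings = character()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  strip <- function(x) {
    if (inherits(x, "scenario_config") || inherits(x, "disparity_config")) {
      x <- unclass(x)
    }
    if (is.list(x)) lapply(x, strip) else x
  }
  jsonlite::write_json(list(seed = seed, config = strip(config),
                            package_version = as.character(utils::packageVersion("smidisparity")),
                            r_version = R.version.string,
                            warnings = warnings,
                            created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
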