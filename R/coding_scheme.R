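#' Covariate coding schemes
#'
#' A coding scheme registers, for every covariate used to predict serious
#' mental illness (SMI), whether it is categorical or continuous, its level
#' set, and the designated reference level. It fixes the design-column
#' naming rule (`variable_level`) and the column order, so that survey
#' microdata and aggregate area profiles are coded identically — the
#' alignment the synthetic small-area projection depends on.
#'
#' @param covariates A named list. Each element describes one covariate and
#'   is itself a list with `kind` (`"categorical"` or `"continuous"`) and,
#'   for categorical covariates, `levels` (character vector) and `reference`
#'   (one of `levels`).
#' @return An object of class `coding_scheme`.
#' @examples
#' scheme <- coding_scheme(list(
#'   gender = list(kind = "categorical",
#'                 levels = c("male", "female"), reference = "male"),
#'   poverty_index = list(kind = "continuous")
#' ))
#' design_columns(scheme)
#' @export
coding_scheme <- function(covariates) {
  if (!is.list(covariates) || is.null(names(covariates)) ||
      any(!nzchar(names(covariates)))) {
    stop("`covariates` must be a named list", call. = FALSE)
  }
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    kind <- cv$kind
    if (is.null(kind) || !kind %in% c("categorical", "continuous")) {
      stop(sprintf("covariate '%s': kind must be 'categorical' or 'continuous'", nm),
           call. = FALSE)
    }
    if (kind == "categorical") {
      if (length(cv$levels) < 2L) {
        stop(sprintf("covariate '%s': categorical covariates need >= 2 levels", nm),
             call. = FALSE)
      }
      if (anyDuplicated(cv$levels)) {
        stop(sprintf("covariate '%s': duplicated levels", nm), call. = FALSE)
      }
      if (is.null(cv$reference) || !cv$reference %in% cv$levels) {
        stop(sprintf("covariate '%s': reference level must be a member of its level set", nm),
             call. = FALSE)
      }
    }
  }
  scheme <- structure(list(covariates = covariates), class = "coding_scheme")
  cols <- design_columns(scheme)
  if (anyDuplicated(cols)) {
    stop("design-column names are not unique across the scheme: ",
         paste(cols[duplicated(cols)], collapse = ", "), call. = FALSE)
  }
  scheme
}

#' Design-column names implied by a coding scheme
#'
#' One indicator column per non-reference level of each categorical
#' covariate (named `variable_level`), continuous covariates by name, in
#' scheme order.
#'
#' @param scheme A [coding_scheme()].
#' @return Character vector of design-column names (intercept excluded).
#' @export
design_columns <- function(scheme) {
  stopifnot(inherits(scheme, "coding_scheme"))
  unlist(lapply(names(scheme$covariates), function(nm) {
    cv <- scheme$covariates[[nm]]
    if (cv$kind == "continuous") return(nm)
    paste(nm, setdiff(cv$levels, cv$reference), sep = "_")
  }), use.names = FALSE)
}

#' The default covariate coding scheme
#'
#' Covers the seven demographic predictors of SMI used throughout the
#' pipeline: age band, gender, race, marital status, employment status,
#' educational attainment, and the income-to-poverty ratio (continuous).
#' Reference levels are the modal/majority categories.
#'
#' @return A [coding_scheme()].
#' @export
default_coding_scheme <- function() {
  coding_scheme(list(
    age_category = list(kind = "categorical",
                        levels = c("18_29", "30_44", "45_59", "60_plus"),
                        reference = "18_29"),
    gender = list(kind = "categorical",
                  levels = c("male", "female"), reference = "male"),
    race = list(kind = "categorical",
                levels = c("White", "Black", "Latinx", "Other"),
                reference = "White"),
    marital_status = list(kind = "categorical",
                          levels = c("married", "never_married", "prev_married"),
                          reference = "married"),
    employment_status = list(kind = "categorical",
                             levels = c("employed", "unemployed", "not_in_labor_force"),
                             reference = "employed"),
    education = list(kind = "categorical",
                     levels = c("lt_highschool", "highschool", "some_college", "college"),
                     reference = "lt_highschool"),
    poverty_index = list(kind = "continuous")
  ))
}

#' Build a design matrix from labelled survey microdata
#'
#' Dummy-codes every categorical covariate against its reference level and
#' passes continuous covariates through, in the column order fixed by the
#' coding scheme. The response is the 0/1 `smi` label.
#'
#' @param labelled_survey Data frame with one row per respondent, containing
#'   an `smi` column (logical or 0/1), every covariate named in `scheme`,
#'   and optionally a `weight` column (missing weights default to 1).
#' @param scheme A [coding_scheme()].
#' @return A list with `X` (numeric design matrix, named columns, no
#'   intercept column), `y` (0/1 response), `weights`, and `scheme`.
#' @export
build_design <- function(labelled_survey, scheme) {
  stopifnot(inherits(scheme, "coding_scheme"))
  if (!"smi" %in% names(labelled_survey)) {
    stop("labelled survey must contain an `smi` column", call. = FALSE)
  }
  missing_cov <- setdiff(names(scheme$covariates), names(labelled_survey))
  if (length(missing_cov)) {
    stop("survey is missing covariate column(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  n <- nrow(labelled_survey)
  cols <- list()
  for (nm in names(scheme$covariates)) {
    cv <- scheme$covariates[[nm]]
    x <- labelled_survey[[nm]]
    if (cv$kind == "continuous") {
      x <- as.numeric(x)
      if (anyNA(x)) stop(sprintf("covariate '%s': missing or non-numeric values", nm),
                         call. = FALSE)
      cols[[nm]] <- x
    } else {
      x <- as.character(x)
      bad <- setdiff(unique(x), cv$levels)
      if (length(bad)) {
        stop(sprintf("covariate '%s': unseen level(s) %s", nm,
                     paste(sQuote(bad), collapse = ", ")), call. = FALSE)
      }
      for (lv in setdiff(cv$levels, cv$reference)) {
        cols[[paste(nm, lv, sep = "_")]] <- as.numeric(x == lv)
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  y <- as.numeric(labelled_survey$smi)
  if (!all(y %in% c(0, 1))) stop("`smi` must be logical or 0/1", call. = FALSE)
  w <- if ("weight" %in% names(labelled_survey)) {
    as.numeric(labelled_survey$weight)
  } else {
    rep(1, n)
  }
  w[is.na(w)] <- 1
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  list(X = X, y = y, weights = w, scheme = scheme)
}

#' Write a coding scheme to a YAML file
#' @param scheme A [coding_scheme()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coding_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "coding_scheme"))
  yaml::write_yaml(scheme$covariates, path)
  invisible(path)
}

#' Read a coding scheme from a YAML file
#' @param path File written by [write_coding_scheme()].
#' @return A [coding_scheme()].
#' @export
read_coding_scheme <- function(path) {
  coding_scheme(yaml::read_yaml(path))
}
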