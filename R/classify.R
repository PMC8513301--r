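#' @keywords internal
"_PACKAGE"

#' The CIDI diagnosis catalogue gating the SMI case definition
#'
#' Eleven indicator items: ten 12-month CIDI diagnoses plus a serious
#' suicide attempt in the past 12 months. Survey files carry one 0/1 column
#' per item, named `diag_<key>`.
#'
#' @return Character vector of catalogue keys.
#' @export
smi_diagnosis_catalogue <- function() {
  c("bipolar_I", "bipolar_II", "mania", "hypomania",
    "major_depressive_disorder", "agoraphobia",
    "generalized_anxiety_disorder", "ptsd",
    "specific_phobia", "social_phobia", "serious_suicide_attempt_12mo")
}

impairment_columns <- function() {
  c("imp_work", "imp_home", "imp_relationships", "imp_social")
}

validate_survey_items <- function(survey) {
  diag_cols <- paste0("diag_", smi_diagnosis_catalogue())
  needed <- c(diag_cols, "days_unable_to_function", impairment_columns(),
              "disorder_duration_months")
  missing <- setdiff(needed, names(survey))
  if (length(missing)) {
    stop("survey is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (dc in diag_cols) {
    v <- survey[[dc]]
    if (anyNA(v) || !all(v %in% c(0, 1, TRUE, FALSE))) {
      stop(sprintf("invalid value in field '%s': diagnosis indicators must be 0/1", dc),
           call. = FALSE)
    }
  }
  days <- survey$days_unable_to_function
  if (anyNA(days) || any(days < 0 | days > 365)) {
    stop("invalid value in field 'days_unable_to_function': must be in [0, 365]",
         call. = FALSE)
  }
  for (ic in impairment_columns()) {
    v <- survey[[ic]]
    if (anyNA(v) || any(v < 0 | v > 10)) {
      stop(sprintf("invalid value in field '%s': impairment ratings must be in [0, 10]", ic),
           call. = FALSE)
    }
  }
  dur <- survey$disorder_duration_months
  if (anyNA(dur) || any(dur < 0)) {
    stop("invalid value in field 'disorder_duration_months': must be >= 0",
         call. = FALSE)
  }
  invisible(survey)
}

#' Classify serious mental illness from survey items
#'
#' Applies the three-criterion SMI case definition to each row of a survey
#' table. A respondent is classified as having SMI iff all of:
#' \describe{
#'   \item{A (diagnosis)}{at least one of the eleven catalogue diagnoses
#'     (see [smi_diagnosis_catalogue()]) is present;}
#'   \item{B (impairment)}{unable to function for at least 120 of the past
#'     365 days, \emph{or} role impairment (work, home, relationships,
#'     social life) rated at least 7 out of 10;}
#'   \item{C (duration)}{the disorder has lasted at least 12 months.}
#' }
#' All thresholds are inclusive (>=). The impairment-rating clause is
#' ambiguous between "any domain >= 7" and "all domains >= 7";
#' `impairment_rule` selects the reading, defaulting to `"any"` (the max
#' over domains), consistent with common severe-role-impairment codings.
#'
#' @param survey Data frame with one row per respondent: `diag_*` indicator
#'   columns for every catalogue key, `days_unable_to_function` (0-365),
#'   impairment ratings `imp_work`, `imp_home`, `imp_relationships`,
#'   `imp_social` (each 0-10), and `disorder_duration_months` (>= 0).
#' @param impairment_rule `"any"` (default): criterion B's rating clause is
#'   satisfied when the maximum rating over the four domains is >= 7;
#'   `"all"`: every domain must be >= 7.
#' @return Logical vector, one element per row.
#' @examples
#' rec <- data.frame(diag_ptsd = 1, days_unable_to_function = 130,
#'                   imp_work = 2, imp_home = 2, imp_relationships = 2,
#'                   imp_social = 2, disorder_duration_months = 14)
#' for (k in setdiff(smi_diagnosis_catalogue(), "ptsd"))
#'   rec[[paste0("diag_", k)]] <- 0
#' classify_smi(rec)  # TRUE: diagnosis + >=120 days + >=12 months
#' @export
classify_smi <- function(survey, impairment_rule = c("any", "all")) {
  impairment_rule <- match.arg(impairment_rule)
  validate_survey_items(survey)
  diag_cols <- paste0("diag_", smi_diagnosis_catalogue())
  diag_any <- rowSums(as.matrix(survey[diag_cols])) > 0
  imp <- as.matrix(survey[impairment_columns()])
  imp_stat <- if (impairment_rule == "any") {
    apply(imp, 1L, max)
  } else {
    apply(imp, 1L, min)
  }
  crit_b <- survey$days_unable_to_function >= 120 | imp_stat >= 7
  crit_c <- survey$disorder_duration_months >= 12
  as.logical(diag_any & crit_b & crit_c)
}

#' Label a survey table with the SMI case definition
#'
#' Row-wise application of [classify_smi()], preserving order and carrying
#' the demographic covariates and survey weight through.
#'
#' @inheritParams classify_smi
#' @param scheme A [coding_scheme()] naming the covariates to carry through;
#'   defaults to [default_coding_scheme()].
#' @return Data frame with columns `respondent_id`, `smi` (logical), the
#'   scheme's covariates, and `weight` (defaulting to 1 where absent).
#' @export
classify_survey <- function(survey, scheme = default_coding_scheme(),
                            impairment_rule = c("any", "all")) {
  impairment_rule <- match.arg(impairment_rule)
  if (!"respondent_id" %in% names(survey)) {
    stop("survey must contain a `respondent_id` column", call. = FALSE)
  }
  if (nrow(survey) == 0L) {
    out <- data.frame(respondent_id = character(), smi = logical(),
                      weight = numeric())
    for (nm in names(scheme$covariates)) out[[nm]] <- character()
    return(out[c("respondent_id", "smi", names(scheme$covariates), "weight")])
  }
  if (anyDuplicated(survey$respondent_id)) {
    stop("duplicate respondent_id values: ",
         paste(unique(survey$respondent_id[duplicated(survey$respondent_id)])[1:3],
               collapse = ", "), call. = FALSE)
  }
  missing_cov <- setdiff(names(scheme$covariates), names(survey))
  if (length(missing_cov)) {
    stop("survey is missing covariate column(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  smi <- classify_smi(survey, impairment_rule)
  out <- data.frame(respondent_id = survey$respondent_id, smi = smi,
                    stringsAsFactors = FALSE)
  for (nm in names(scheme$covariates)) out[[nm]] <- survey[[nm]]
  out$weight <- if ("weight" %in% names(survey)) {
    w <- as.numeric(survey$weight)
    w[is.na(w)] <- 1
    w
  } else {
    rep(1, nrow(survey))
  }
  out
}
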