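#' City-level share of incidents involving persons with SMI
#'
#' For each city-year (optionally by outcome), the fraction of incidents
#' whose subject was flagged as a person with serious mental illness.
#'
#' @param incidents Data frame with columns `city_id`, `year`, `outcome`
#'   (`force`/`injury`), `smi_flag` (logical or 0/1).
#' @param outcome Restrict to one outcome; `NULL` pools outcomes.
#' @return Data frame `city_id`, `year`, `n_incidents`, `share_events_smi`.
#'   City-years with zero incidents get `NA` with a warning.
#' @export
city_shares <- function(incidents, outcome = NULL) {
  needed <- c("city_id", "year", "smi_flag")
  missing <- setdiff(needed, names(incidents))
  if (length(missing)) {
    stop("incidents missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- incidents
  if (!is.null(outcome)) d <- d[d$outcome == outcome, , drop = FALSE]
  if (nrow(d) == 0L) {
    warning("no incidents after filtering; returning empty table", call. = FALSE)
    return(data.frame(city_id = character(), year = integer(),
                      n_incidents = integer(), share_events_smi = numeric()))
  }
  agg <- stats::aggregate(cbind(n_incidents = rep(1L, nrow(d)),
                                n_smi = as.numeric(d$smi_flag)),
                          by = list(city_id = d$city_id, year = d$year), FUN = sum)
  agg$n_incidents <- as.integer(agg$n_incidents)
  agg$share_events_smi <- ifelse(agg$n_incidents > 0,
                                 agg$n_smi / agg$n_incidents, NA_real_)
  if (anyNA(agg$share_events_smi)) {
    warning("city-year(s) with zero incidents: share undefined", call. = FALSE)
  }
  agg <- agg[order(agg$city_id, agg$year),
             c("city_id", "year", "n_incidents", "share_events_smi")]
  rownames(agg) <- NULL
  agg
}

#' Overrepresentation ratio
#'
#' The raw disparity measure behind the city-level summaries: the share of
#' incidents attributed to a group divided by the group's estimated
#' population prevalence. Scale-free in the incident counts.
#'
#' @param share Fraction of incidents attributed to the group, in `[0, 1]`.
#' @param prevalence Group population prevalence, in `(0, 1]`.
#' @return `share / prevalence` (vectorized).
#' @export
overrepresentation <- function(share, prevalence) {
  if (any(prevalence <= 0)) stop("prevalence must be > 0", call. = FALSE)
  share / prevalence
}

#' Homeless-adjusted SMI prevalence
#'
#' City prevalence estimates built from housed survey frames miss homeless
#' residents, among whom SMI rates are far higher (reported as high as
#' 40%). This adds an assumed-rate homeless contribution to both the SMI
#' count and the population denominator.
#'
#' @param n_smi_housed Estimated SMI count in the housed adult population.
#' @param adult_pop Housed adult population.
#' @param n_homeless Homeless population count.
#' @param smi_rate_homeless Assumed SMI rate among homeless residents, in
#'   `[0, 1]`; default 0.40.
#' @return Adjusted prevalence
#'   `(n_smi_housed + smi_rate_homeless * n_homeless) / (adult_pop + n_homeless)`.
#' @export
adjust_prevalence_homeless <- function(n_smi_housed, adult_pop, n_homeless,
                                       smi_rate_homeless = 0.40) {
  if (any(c(n_smi_housed, adult_pop, n_homeless) < 0)) {
    stop("all inputs must be >= 0", call. = FALSE)
  }
  if (any(smi_rate_homeless < 0 | smi_rate_homeless > 1)) {
    stop("smi_rate_homeless must be in [0, 1]", call. = FALSE)
  }
  denom <- adult_pop + n_homeless
  if (any(denom == 0)) stop("adult_pop + n_homeless must be > 0", call. = FALSE)
  (n_smi_housed + smi_rate_homeless * n_homeless) / denom
}

#' City-level disparity summaries
#'
#' Joins incident shares with city prevalence estimates and computes the
#' overrepresentation ratio per city-year. With `most_recent_only = TRUE`
#' only each city's latest year with data is kept (the headline view);
#' otherwise all city-years are returned. Cities with no incidents for the
#' requested outcome (e.g. a department not recording injuries) are
#' skipped with a message, not an error.
#'
#' @param incidents Incident-level table (see [city_shares()]).
#' @param prevalence Data frame with `area_id` (city), `year`, `p_smi` —
#'   city-level rows from [project_all()] (or any table with those columns;
#'   a `city_id` column is accepted in place of `area_id`).
#' @param outcome `"force"` (default) or `"injury"`.
#' @param most_recent_only Keep only each city's most recent year.
#' @return Data frame: `city_id`, `year`, `n_incidents`, `prevalence_smi`,
#'   `share_events_smi`, `overrepresentation`.
#' @export
city_summary <- function(incidents, prevalence, outcome = "force",
                         most_recent_only = TRUE) {
  if ("area_id" %in% names(prevalence) && !"city_id" %in% names(prevalence)) {
    prevalence$city_id <- prevalence$area_id
  }
  needed <- c("city_id", "year", "p_smi")
  missing <- setdiff(needed, names(prevalence))
  if (length(missing)) {
    stop("prevalence missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  shares <- city_shares(incidents, outcome = outcome)
  skipped <- setdiff(unique(prevalence$city_id), unique(shares$city_id))
  if (length(skipped)) {
    message(sprintf("skipping city(ies) with no '%s' incidents: %s",
                    outcome, paste(skipped, collapse = ", ")))
  }
  m <- merge(shares, prevalence[needed], by = c("city_id", "year"))
  if (nrow(m) == 0L) {
    stop("no city-years shared between incidents and prevalence", call. = FALSE)
  }
  m$prevalence_smi <- m$p_smi
  m$p_smi <- NULL
  m$overrepresentation <- overrepresentation(m$share_events_smi, m$prevalence_smi)
  if (most_recent_only) {
    keep <- unlist(lapply(split(seq_len(nrow(m)), m$city_id),
                          function(idx) idx[which.max(m$year[idx])]))
    m <- m[sort(keep), , drop = FALSE]
  }
  m <- m[order(m$city_id, m$year), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Pooled and across-city share statistics
#'
#' Two complementary summaries of the SMI share of incidents: the pooled
#' share (incident-weighted, as if all cities were one sample) and the
#' unweighted across-city mean with its SD (the cross-city dispersion).
#'
#' @param summary_table Output of [city_summary()].
#' @return One-row data frame: `pooled_share`, `mean_share`, `sd_share`,
#'   `n_cities`.
#' @export
pooled_share_stats <- function(summary_table) {
  st <- summary_table[!is.na(summary_table$share_events_smi), , drop = FALSE]
  data.frame(
    pooled_share = sum(st$share_events_smi * st$n_incidents) / sum(st$n_incidents),
    mean_share = mean(st$share_events_smi),
    sd_share = stats::sd(st$share_events_smi),
    n_cities = length(unique(st$city_id))
  )
}
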