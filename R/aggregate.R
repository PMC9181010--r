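# Cohort analytics over extracted records: prevalence by sex and age
# bins, and extent/location distributions per disease.

#' The fixed age-bin scheme
#'
#' Partitions ages 18-100 into 18-19, 20-29, ..., 70-79, >=80 with no
#' overlap.
#'
#' @return Data frame with `label`, `lo`, `hi` (inclusive bounds).
#' @export
age_bins <- function() {
  data.frame(
    label = c("18-19", "20-29", "30-39", "40-49", "50-59", "60-69",
              "70-79", ">=80"),
    lo = c(18, 20, 30, 40, 50, 60, 70, 80),
    hi = c(19, 29, 39, 49, 59, 69, 79, 100),
    stringsAsFactors = FALSE
  )
}

age_bin_label <- function(age) {
  b <- age_bins()
  idx <- vapply(age, function(a) which(b$lo <= a & a <= b$hi)[1], integer(1))
  b$label[idx]
}

#' Disease prevalence by sex and age bin
#'
#' For every stratum (the two sexes and the eight age bins) and every
#' disease, the number of reports with the disease present and the
#' percentage of the stratum's reports (2 decimals).  Denominators are
#' reports, not unique patients, unless `dedup_patients` is set, in which
#' case one report per patient (the earliest exam) is kept first.
#'
#' @param records Disease records (pipeline output or gold).
#' @param reports EGD report data frame supplying the demographics.
#' @param dedup_patients Keep one report per patient (default `FALSE`).
#' @return Data frame with `stratum_type` (`SEX`/`AGE`), `stratum`,
#'   `n_stratum`, `disease`, `n_present`, `pct`.  Records whose
#'   `report_id` has no demographics are excluded; their count is
#'   attached as attribute `n_unresolved` (with a warning when positive).
#' @export
prevalence_table <- function(records, reports, dedup_patients = FALSE) {
  if (dedup_patients) {
    ord <- order(reports$patient_id, reports$exam_date)
    reports <- reports[ord, , drop = FALSE]
    reports <- reports[!duplicated(reports$patient_id), , drop = FALSE]
  }
  known <- records$report_id %in% reports$report_id
  n_unresolved <- length(unique(records$report_id[!known]))
  if (n_unresolved)
    warning(n_unresolved, " record report id(s) have no demographics; excluded")
  records <- records[known, , drop = FALSE]
  records <- records[records$report_id %in% reports$report_id, , drop = FALSE]

  demo <- reports[, c("report_id", "sex", "age")]
  demo$age_bin <- age_bin_label(demo$age)
  idx <- match(records$report_id, demo$report_id)
  records$sex <- demo$sex[idx]
  records$age_bin <- demo$age_bin[idx]

  strata <- rbind(
    data.frame(stratum_type = "SEX", stratum = c("MALE", "FEMALE"),
               stringsAsFactors = FALSE),
    data.frame(stratum_type = "AGE", stratum = age_bins()$label,
               stringsAsFactors = FALSE)
  )
  rows <- list()
  for (s in seq_len(nrow(strata))) {
    if (strata$stratum_type[s] == "SEX") {
      in_stratum_reports <- demo$sex == strata$stratum[s]
      in_stratum_records <- records$sex == strata$stratum[s]
    } else {
      in_stratum_reports <- demo$age_bin == strata$stratum[s]
      in_stratum_records <- records$age_bin == strata$stratum[s]
    }
    n_stratum <- sum(in_stratum_reports)
    for (d in GASTRIC_DISEASES) {
      n_present <- sum(in_stratum_records & records$disease == d & records$present)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum_type = strata$stratum_type[s], stratum = strata$stratum[s],
        n_stratum = n_stratum, disease = d, n_present = n_present,
        pct = if (n_stratum > 0) round(100 * n_present / n_stratum, 2) else 0,
        empty_stratum = n_stratum == 0,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_unresolved") <- n_unresolved
  out
}

#' Extent distribution per gastritis label
#'
#' Percentage of present reports at each extent level; the denominator is
#' the number of reports with the disease present.  Because extent is
#' single-valued, the E1/E2/E3/UNSPECIFIED shares sum to 100 exactly
#' (when any report is present).
#'
#' @param records Disease records.
#' @return Data frame with `disease`, `level`, `n`, `pct`.
#' @export
extent_distribution <- function(records) {
  rows <- list()
  for (d in GASTRITIS_DISEASES) {
    sub <- records[records$disease == d & records$present, , drop = FALSE]
    denom <- nrow(sub)
    for (lev in EXTENT_LEVELS) {
      n <- sum(sub$extent == lev)
      rows[[length(rows) + 1L]] <- data.frame(
        disease = d, level = lev, n = n,
        pct = if (denom > 0) 100 * n / denom else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Location distribution per non-gastritis disease
#'
#' Percentage of present reports mentioning each region; the denominator
#' is the number of reports with the disease present.  Multi-location
#' lesions count under every region they occupy, so the percentages may
#' sum above 100; unspecified locations make them sum below 100.
#'
#' @param records Disease records.
#' @return Data frame with `disease`, `level` (region), `n`, `pct`.
#' @export
location_distribution <- function(records) {
  rows <- list()
  for (d in LESION_DISEASES) {
    sub <- records[records$disease == d & records$present, , drop = FALSE]
    denom <- nrow(sub)
    for (r in STOMACH_REGIONS) {
      n <- sum(vapply(sub$locations, function(l) r %in% l, logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        disease = d, level = r, n = n,
        pct = if (denom > 0) 100 * n / denom else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
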