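#' Patient record fields
#'
#' Endpoint classification operates on one-row records (or data frames with
#' one row per patient) using these columns:
#' \describe{
#'   \item{smwt_base, smwt_30d, smwt_6m}{6-min walk distances, metres.}
#'   \item{ntprobnp_base, ntprobnp_30d, ntprobnp_6m}{NT-proBNP, pg/ml.}
#'   \item{nyha_pre, nyha_post}{NYHA class, 1-4.}
#'   \item{kccq_pre, kccq_post}{KCCQ score, 0-100.}
#'   \item{death_time}{Days from TAVI to death, `NA` if alive in follow-up.}
#'   \item{death_cause}{`"heart_failure"`, `"other"` or `"none"`.}
#'   \item{hf_event_after_30d}{Logical: heart-failure event after the 30-day
#'     evaluation.}
#' }
#' Missing measurements are `NA`; they are never imputed.
#'
#' @name patient_record
NULL

improved_by_criteria <- function(walk_base, walk_fu, ntp_base, ntp_fu) {
  # disjunctive rule: >=10% walk gain, else >=50% NT-proBNP reduction
  walk_ok <- !is.na(walk_base) && !is.na(walk_fu)
  ntp_ok <- !is.na(ntp_base) && !is.na(ntp_fu)
  if (!walk_ok && !ntp_ok) return(NULL)
  if (walk_ok && walk_fu >= 1.10 * walk_base) return("walk_test")
  if (ntp_ok && ntp_fu <= 0.50 * ntp_base) return("biomarker")
  "neither"
}

#' Classify objective functional improvement
#'
#' Applies the study's 6-month objective-improvement rule to one patient:
#' improvement is an increase of at least 10% in the 6-min walk distance, or
#' -- when that is not met -- a reduction of at least 50% in NT-proBNP, both
#' relative to pre-TAVI.  Death handling: death before day 30 from heart
#' failure counts as not improved, death before day 30 from another cause
#' excludes the patient (no functional evaluation exists); death between the
#' 30-day evaluation and 6 months is classified on the 30-day values with the
#' same two criteria, overridden to not improved if the patient suffered from
#' or died of heart failure after that evaluation.
#'
#' @param record One patient record (named list or one-row data frame);
#'   see [patient_record].
#' @param walk_gain Walk-test threshold as a proportional gain (default 0.10).
#' @param ntp_drop NT-proBNP threshold as a proportional reduction (default 0.50).
#' @return List with `objective` (`"improved"`, `"not_improved"`,
#'   `"excluded"`) and `reason`.
#' @export
classify_objective <- function(record, walk_gain = 0.10, ntp_drop = 0.50) {
  r <- as.list(record)
  num <- function(f) if (is.null(r[[f]])) NA_real_ else as.numeric(r[[f]])
  dtime <- num("death_time")
  cause <- as.character(r$death_cause %||% "none")
  if (is.na(dtime)) cause <- "none"

  crit <- function(wb, wf, nb, nf) {
    walk_ok <- !is.na(wb) && !is.na(wf)
    ntp_ok <- !is.na(nb) && !is.na(nf)
    if (!walk_ok && !ntp_ok) return(NULL)
    if (walk_ok && wf >= (1 + walk_gain) * wb) return("walk_test")
    if (ntp_ok && nf <= (1 - ntp_drop) * nb) return("biomarker")
    "neither"
  }

  if (!is.na(dtime) && dtime < 30) {
    if (cause == "heart_failure")
      return(list(objective = "not_improved", reason = "death_before_30d_hf"))
    return(list(objective = "excluded", reason = "death_before_30d_other_excluded"))
  }
  if (!is.na(dtime) && dtime <= 182.5) {
    # died between the 30-day evaluation and the 6-month landmark
    if (isTRUE(as.logical(r$hf_event_after_30d)) || cause == "heart_failure")
      return(list(objective = "not_improved", reason = "death_30d_to_6m_hf"))
    hit <- crit(num("smwt_base"), num("smwt_30d"),
                num("ntprobnp_base"), num("ntprobnp_30d"))
    if (is.null(hit))
      stop_vp("patient %s died before 6 months but has no 30-day walk-test or NT-proBNP pair",
              as.character(r$id %||% "?"))
    obj <- if (hit %in% c("walk_test", "biomarker")) "improved" else "not_improved"
    return(list(objective = obj, reason = "death_30d_to_6m_carryforward"))
  }
  hit <- crit(num("smwt_base"), num("smwt_6m"),
              num("ntprobnp_base"), num("ntprobnp_6m"))
  if (is.null(hit)) {
    miss <- c("smwt_base", "smwt_6m", "ntprobnp_base", "ntprobnp_6m")
    miss <- miss[vapply(miss, function(f) is.na(num(f)), logical(1))]
    stop_vp("survivor %s is missing both 6-month criteria pairs (missing: %s)",
            as.character(r$id %||% "?"), paste(miss, collapse = ", "))
  }
  list(objective = if (hit %in% c("walk_test", "biomarker")) "improved" else "not_improved",
       reason = hit)
}

#' Classify subjective improvement
#'
#' Subjective improvement is a positive change of at least one NYHA class
#' and/or a gain of at least 10 KCCQ points; `"missing"` when neither pair is
#' available.
#'
#' @param record One patient record; see [patient_record].
#' @param kccq_gain KCCQ threshold in points (default 10).
#' @return `"improved"`, `"not_improved"` or `"missing"`.
#' @export
classify_subjective <- function(record, kccq_gain = 10) {
  r <- as.list(record)
  num <- function(f) if (is.null(r[[f]])) NA_real_ else as.numeric(r[[f]])
  nyha <- c(num("nyha_pre"), num("nyha_post"))
  kccq <- c(num("kccq_pre"), num("kccq_post"))
  nyha_ok <- !anyNA(nyha); kccq_ok <- !anyNA(kccq)
  if (!nyha_ok && !kccq_ok) return("missing")
  if (nyha_ok && nyha[2] <= nyha[1] - 1) return("improved")
  if (kccq_ok && kccq[2] >= kccq[1] + kccq_gain) return("improved")
  "not_improved"
}

#' Classify a whole cohort
#'
#' Applies [classify_objective()] and [classify_subjective()] row-wise.
#'
#' @param records Data frame, one patient per row; see [patient_record].
#' @param ... Passed to the per-patient classifiers.
#' @return `records` with `objective`, `reason` and `subjective` columns
#'   appended.
#' @export
classify_cohort <- function(records, ...) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  obj <- lapply(seq_len(nrow(records)), function(i) classify_objective(records[i, ], ...))
  records$objective <- vapply(obj, `[[`, character(1), "objective")
  records$reason <- vapply(obj, `[[`, character(1), "reason")
  records$subjective <- vapply(seq_len(nrow(records)),
                               function(i) classify_subjective(records[i, ]), character(1))
  records
}

#' Tabulate improvement outcomes
#'
#' Counts improved / not improved / excluded patients and the improvement
#' percentages over the non-excluded denominator, rounded to one decimal.
#'
#' @param labels Data frame from [classify_cohort()] (or any data frame with
#'   `objective` and optionally `subjective` columns).
#' @return List with `counts`, `n_analysed` (non-excluded), `pct_objective`
#'   and (when available) `pct_subjective` (over non-excluded patients with a
#'   non-missing subjective label).
#' @export
tabulate_outcomes <- function(labels) {
  if (NROW(labels) == 0L) stop_vp("no records to tabulate")
  obj <- labels$objective
  if (is.null(obj)) stop_vp("labels must have an 'objective' column")
  counts <- c(improved = sum(obj == "improved"),
              not_improved = sum(obj == "not_improved"),
              excluded = sum(obj == "excluded"))
  n_eval <- counts[["improved"]] + counts[["not_improved"]]
  if (n_eval == 0L) stop_vp("no analysable (non-excluded) records")
  out <- list(counts = counts, n_analysed = n_eval,
              pct_objective = round(100 * counts[["improved"]] / n_eval, 1))
  if (!is.null(labels$subjective)) {
    sub <- labels$subjective[obj != "excluded"]
    sub <- sub[sub != "missing"]
    if (length(sub))
      out$pct_subjective <- round(100 * mean(sub == "improved"), 1)
  }
  out
}
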