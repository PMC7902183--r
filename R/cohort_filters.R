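# Visit-level cohort selection. Four rules, applied in a fixed order with a
# full audit trail:
#   1. visits beyond the follow-up horizon are dropped (long follow-up would
#      give a few subjects extra leverage in the trajectory models);
#   2. subjects with fewer than `min_visits` remaining visits are dropped;
#   3. subjects with abnormal hearing sensitivity (> 25 dB HL at any of
#      0.5/1/2/4 kHz in either ear on any retained visit) or abnormal middle
#      ear function (tympanogram type outside A/As/Ad, peak pressure outside
#      [-100, +50] daPa, static admittance outside [0.3, 1.7] mmho, or missing
#      tympanometry) are dropped;
#   4. subjects with any positive history flag (ear drainage, concussion,
#      noise/chemical exposure, neurological disease, mental illness,
#      ototoxic antibiotics, chemotherapy) are dropped.

#' Column name conventions for visit-level cohort tables
#'
#' @return Named list of required column groups: identifiers, audiogram
#'   thresholds per ear (dB HL at 0.5/1/2/4 kHz), tympanometry, and history
#'   flags.
#' @export
cohort_columns <- function() {
  list(
    id = c("subject_id", "hiv_status", "visit_time", "age_at_visit"),
    audiogram = c("aud_r_500", "aud_r_1000", "aud_r_2000", "aud_r_4000",
                  "aud_l_500", "aud_l_1000", "aud_l_2000", "aud_l_4000"),
    tymp = c("tymp_type", "tymp_pressure", "tymp_admittance"),
    history = c("hx_ear_drainage", "hx_concussion", "hx_noise_chemical",
                "hx_neuro_disease", "hx_mental_illness", "hx_ototoxic",
                "hx_chemotherapy")
  )
}

#' Pure tone average (PTA)
#'
#' Arithmetic mean of the audiometric thresholds at 0.5, 1, 2 and 4 kHz for
#' one ear. A missing frequency yields a missing PTA.
#'
#' @param t500,t1000,t2000,t4000 Thresholds in dB HL (vectorized).
#' @return PTA in dB HL.
#' @examples
#' compute_pta(0, 5, 10, 25) # 10
#' @export
compute_pta <- function(t500, t1000, t2000, t4000) {
  (t500 + t1000 + t2000 + t4000) / 4
}

#' Add per-ear PTA columns to a cohort table
#'
#' @param cohort Data frame with the audiogram columns of [cohort_columns()].
#' @return `cohort` with `pta_r` and `pta_l` columns added.
#' @export
add_pta <- function(cohort) {
  cohort$pta_r <- compute_pta(cohort$aud_r_500, cohort$aud_r_1000,
                              cohort$aud_r_2000, cohort$aud_r_4000)
  cohort$pta_l <- compute_pta(cohort$aud_l_500, cohort$aud_l_1000,
                              cohort$aud_l_2000, cohort$aud_l_4000)
  cohort
}

#' Apply the longitudinal data-selection rules
#'
#' @param cohort Visit-level data frame using the [cohort_columns()] naming,
#'   sorted by `visit_time` within subject (enforced).
#' @param horizon_days Follow-up horizon; visits later than this are dropped.
#'   Default 1278 days (3.5 years at 365.25 days/year).
#' @param min_visits Minimum retained visits per subject ("3 or less" visits
#'   excludes, hence >= 4 by default).
#' @param hearing_limit_db Maximum admissible threshold at 0.5-4 kHz, dB HL.
#' @param tymp_types Admissible tympanogram types.
#' @param tymp_pressure_range Admissible peak pressure, daPa.
#' @param tymp_admittance_range Admissible static admittance, mmho.
#' @param history_scope `"any_visit"` (default; a positive flag at any
#'   retained visit excludes) or `"baseline"` (first retained visit only).
#' @return List with `cohort` (the retained visits) and `audit`, a
#'   `filter_audit` object with per-rule exclusion counts, per-subject
#'   reasons, and retained totals.
#' @export
apply_filters <- function(cohort,
                          horizon_days = 1278,
                          min_visits = 4,
                          hearing_limit_db = 25,
                          tymp_types = c("A", "As", "Ad"),
                          tymp_pressure_range = c(-100, 50),
                          tymp_admittance_range = c(0.3, 1.7),
                          history_scope = c("any_visit", "baseline")) {
  history_scope <- match.arg(history_scope)
  cols <- cohort_columns()
  need <- unlist(cols, use.names = FALSE)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort lacks required columns: ", paste(missing_cols, collapse = ", "))
  n_subj_in <- length(unique(cohort$subject_id))
  n_visits_in <- nrow(cohort)
  if (n_visits_in == 0) {
    audit <- empty_audit()
    return(list(cohort = cohort, audit = audit))
  }
  unsorted <- tapply(cohort$visit_time, cohort$subject_id,
                     function(t) is.unsorted(t, strictly = TRUE))
  if (any(unsorted))
    stop("visits must be strictly ordered by visit_time within subject: ",
         paste(names(unsorted)[unsorted], collapse = ", "))

  reasons <- data.frame(subject_id = character(0), rule = character(0),
                        reason = character(0))
  note <- function(ids, rule, why) {
    if (length(ids) == 0) return(invisible(NULL))
    reasons <<- rbind(reasons, data.frame(subject_id = ids, rule = rule,
                                          reason = why))
  }

  # Rule 1: truncate follow-up
  beyond <- cohort$visit_time > horizon_days
  visits_dropped_horizon <- sum(beyond)
  kept <- cohort[!beyond, , drop = FALSE]

  # Rule 2: minimum visit count on the retained visits. Subjects who would
  # have met the count but lost visits to the horizon are attributed to the
  # horizon rule in the audit; the retained set is identical either way.
  ids_all <- unique(as.character(cohort$subject_id))
  nv_total <- table(as.character(cohort$subject_id))
  nv_kept <- table(factor(as.character(kept$subject_id), levels = ids_all))
  few <- ids_all[nv_kept < min_visits]
  few_horizon <- few[nv_total[few] >= min_visits]
  few_always <- setdiff(few, few_horizon)
  note(few_horizon, "horizon",
       sprintf("fewer than %d visits after horizon truncation", min_visits))
  note(few_always, "min_visits", sprintf("fewer than %d visits", min_visits))
  kept <- kept[!(kept$subject_id %in% few), , drop = FALSE]

  # Rule 3: hearing sensitivity and middle ear function, any retained visit
  aud <- as.matrix(kept[cols$audiogram])
  bad_hearing <- rowSums(aud > hearing_limit_db, na.rm = TRUE) > 0 |
    rowSums(is.na(aud)) > 0
  tymp_missing <- is.na(kept$tymp_type) | is.na(kept$tymp_pressure) |
    is.na(kept$tymp_admittance)
  bad_tymp <- !tymp_missing &
    (!(kept$tymp_type %in% tymp_types) |
       kept$tymp_pressure < tymp_pressure_range[1] |
       kept$tymp_pressure > tymp_pressure_range[2] |
       kept$tymp_admittance < tymp_admittance_range[1] |
       kept$tymp_admittance > tymp_admittance_range[2])
  ids_hear <- unique(kept$subject_id[bad_hearing])
  ids_tymp <- setdiff(unique(kept$subject_id[bad_tymp]), ids_hear)
  ids_tmiss <- setdiff(unique(kept$subject_id[tymp_missing]),
                       c(ids_hear, ids_tymp))
  note(ids_hear, "hearing", sprintf("threshold > %g dB HL at 0.5-4 kHz", hearing_limit_db))
  note(ids_tymp, "hearing", "tympanometry outside acceptance limits")
  note(ids_tmiss, "hearing", "tympanometry missing")
  drop3 <- c(ids_hear, ids_tymp, ids_tmiss)
  kept <- kept[!(kept$subject_id %in% drop3), , drop = FALSE]

  # Rule 4: positive history flags
  scope <- if (history_scope == "baseline") {
    first <- !duplicated(kept$subject_id)
    kept[first, , drop = FALSE]
  } else kept
  hx <- as.matrix(scope[cols$history])
  storage.mode(hx) <- "logical"
  bad_hx <- rowSums(hx, na.rm = TRUE) > 0
  ids_hx <- unique(scope$subject_id[bad_hx])
  note(ids_hx, "history", "positive exclusionary history flag")
  kept <- kept[!(kept$subject_id %in% ids_hx), , drop = FALSE]

  audit <- structure(list(
    n_subjects_in = n_subj_in,
    n_visits_in = n_visits_in,
    visits_dropped_horizon = visits_dropped_horizon,
    subjects_dropped_horizon = length(few_horizon),
    subjects_dropped_min_visits = length(few_always),
    subjects_dropped_hearing = length(drop3),
    subjects_dropped_history = length(ids_hx),
    n_subjects_out = length(unique(kept$subject_id)),
    n_visits_out = nrow(kept),
    reasons = reasons
  ), class = "filter_audit")
  rownames(kept) <- NULL
  list(cohort = kept, audit = audit)
}

empty_audit <- function() {
  structure(list(
    n_subjects_in = 0L, n_visits_in = 0L, visits_dropped_horizon = 0L,
    subjects_dropped_horizon = 0L,
    subjects_dropped_min_visits = 0L, subjects_dropped_hearing = 0L,
    subjects_dropped_history = 0L, n_subjects_out = 0L, n_visits_out = 0L,
    reasons = data.frame(subject_id = character(0), rule = character(0),
                         reason = character(0))
  ), class = "filter_audit")
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("<filter_audit>\n")
  cat(sprintf("  subjects in/out: %d / %d   visits in/out: %d / %d\n",
              x$n_subjects_in, x$n_subjects_out, x$n_visits_in, x$n_visits_out))
  cat(sprintf("  visits beyond horizon: %d\n", x$visits_dropped_horizon))
  cat(sprintf(
    "  excluded: horizon %d | <min visits %d | hearing/middle ear %d | history %d\n",
    x$subjects_dropped_horizon, x$subjects_dropped_min_visits,
    x$subjects_dropped_hearing, x$subjects_dropped_history))
  invisible(x)
}
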