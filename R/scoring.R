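# Normative scoring against the HIV-negative reference, the combination
# central-auditory (CAT) score, last-visit quantile grouping, and the three
# global composites (executive, speed, CAT).

#' Default outcome directions
#'
#' Named vector mapping each outcome column to `"higher_better"` or
#' `"lower_better"`. Lower-is-better variables (thresholds, SRTs, response
#' times, error counts) are sign-flipped during z-scoring so that a higher z
#' always means better performance.
#'
#' @return Named character vector.
#' @export
outcome_directions <- function() {
  c(gap_ms = "lower_better",        # gap-detection threshold, ms
    hint_snr = "lower_better",      # HINT composite SRT, dB SNR
    tdt_snr = "lower_better",       # digit-triplet SRT, dB SNR
    moca = "higher_better",         # MoCA total (analyzed raw, normable anyway)
    tova_rt = "lower_better",       # TOVA mean correct response time, ms
    tova_exg_mu = "lower_better",   # TOVA ex-Gaussian mu, ms
    tova_acs = "higher_better",     # TOVA attention comparison score
    gml_speed = "higher_better",    # Groton maze learning, moves per second
    gml_errors = "lower_better",    # Groton maze learning, total errors
    ocl_acc = "higher_better",      # One Card Learning accuracy
    onb_rt = "lower_better",        # One Back reaction time, ms
    cpal_acc = "higher_better")     # Continuous paired associate learning accuracy
}

#' Components of the combination CAT score and the global composites
#'
#' The combination CAT score and global CAT score use the three central
#' auditory tests; the global executive score uses the Cogstate subtests
#' except One Back; the global speed score uses the TOVA speed measures plus
#' One Back. The attention comparison score enters no composite and is
#' analyzed standalone.
#'
#' @return Named list of character vectors of outcome column names.
#' @export
composite_components <- function() {
  list(
    cat = c("gap_ms", "hint_snr", "tdt_snr"),
    executive = c("gml_speed", "gml_errors", "ocl_acc", "cpal_acc"),
    speed = c("tova_rt", "tova_exg_mu", "onb_rt")
  )
}

reference_visit_rows <- function(cohort, reference_visit) {
  split_idx <- split(seq_len(nrow(cohort)), cohort$subject_id)
  pick <- vapply(split_idx, function(ix) {
    t <- cohort$visit_time[ix]
    if (reference_visit == "last") ix[which.max(t)] else ix[which.min(t)]
  }, integer(1))
  unname(pick)
}

#' Build normative reference statistics from the HIV-negative group
#'
#' Mean and SD of each variable over the HIV-negative subjects' reference
#' visits. The reference visit defaults to each subject's last retained
#' visit, aligning the norms with the visit used for grouping (so the norms
#' and the grouped scores sit at the same stage of any learning effect);
#' `"baseline"` uses the first visit instead.
#'
#' @param cohort Visit-level data frame with `subject_id`, `hiv_status`,
#'   `visit_time`, and the outcome columns.
#' @param variables Outcome columns to norm; defaults to
#'   `names(outcome_directions())` intersected with `names(cohort)`.
#' @param directions Named direction vector; defaults to
#'   [outcome_directions()].
#' @param reference_visit `"last"` (default) or `"baseline"`.
#' @return An `aud_norms` data frame: `variable`, `mean`, `sd`, `direction`,
#'   `n`, `normable` (FALSE when the variable is constant or observed on
#'   fewer than two reference subjects).
#' @export
build_norms <- function(cohort, variables = NULL,
                        directions = outcome_directions(),
                        reference_visit = c("last", "baseline")) {
  reference_visit <- match.arg(reference_visit)
  if (is.null(variables))
    variables <- intersect(names(outcome_directions()), names(cohort))
  stopifnot(length(variables) > 0, all(variables %in% names(cohort)))
  ref <- cohort[cohort$hiv_status == "negative", , drop = FALSE]
  if (length(unique(ref$subject_id)) < 2)
    stop("need at least 2 HIV-negative subjects to build norms")
  ref <- ref[reference_visit_rows(ref, reference_visit), , drop = FALSE]
  out <- lapply(variables, function(v) {
    x <- ref[[v]][!is.na(ref[[v]])]
    m <- if (length(x) > 0) mean(x) else NA_real_
    s <- if (length(x) > 1) stats::sd(x) else NA_real_
    dir <- if (v %in% names(directions)) directions[[v]] else "higher_better"
    data.frame(variable = v, mean = m, sd = s, direction = dir,
               n = length(x),
               normable = length(x) >= 2 && is.finite(s) && s > 0)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("aud_norms", "data.frame"),
            reference_visit = reference_visit)
}

#' Transform a value to a direction-harmonized z-score
#'
#' `(value - mean) / sd`, sign-flipped for lower-is-better variables so that
#' higher z means better performance for every variable. Missing values stay
#' missing.
#'
#' @param value Numeric vector of raw scores.
#' @param norms An [build_norms()] table.
#' @param variable Variable name; must be normable.
#' @return z-scores.
#' @export
zscore <- function(value, norms, variable) {
  row <- norms[norms$variable == variable, , drop = FALSE]
  if (nrow(row) != 1) stop("variable not present in norms: ", variable)
  if (!row$normable) stop("variable is not normable (zero variance): ", variable)
  z <- (value - row$mean) / row$sd
  if (row$direction == "lower_better") -z else z
}

#' Add z-score columns for every normable variable
#'
#' @param cohort Visit-level data frame.
#' @param norms An [build_norms()] table.
#' @param prefix Prefix for the new columns (default `"z_"`).
#' @return `cohort` with one `z_<variable>` column per normable variable.
#' @export
apply_norms <- function(cohort, norms, prefix = "z_") {
  for (v in norms$variable[norms$normable])
    cohort[[paste0(prefix, v)]] <- zscore(cohort[[v]], norms, v)
  cohort
}

#' Combination CAT score
#'
#' Unweighted mean of the three direction-harmonized CAT z-scores (gap
#' detection, HINT composite, digit triplet). Any missing component yields a
#' missing combination score — grouping demands complete CAT data.
#'
#' @param z_gap,z_hint_composite,z_tdt z-scores (vectorized).
#' @return Combination score in z-units.
#' @export
combination_cat_score <- function(z_gap, z_hint_composite, z_tdt) {
  (z_gap + z_hint_composite + z_tdt) / 3
}

#' Per-subject last-visit rows
#'
#' @param cohort Visit-level data frame with `subject_id` and `visit_time`.
#' @return The subset of rows at each subject's maximum `visit_time`.
#' @export
last_visit_rows <- function(cohort) {
  idx <- reference_visit_rows(cohort, "last")
  out <- cohort[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign study groups from last-visit combination CAT scores
#'
#' Quantile cut-points at `probs` (default 0.20 / 0.80) are computed over the
#' chosen scope's combination scores (default: the entire cohort, HIV-negative
#' included). HIV-positive subjects at or below the lower cut become
#' `BottomCATs`, at or above the upper cut `TopCATs`, the rest remain
#' `HIV-positive`; HIV-negative subjects always stay `HIV-negative`.
#' Boundary-equal scores go to the extreme group, which (with ties) is how
#' unequal group sizes can arise.
#'
#' @param scores Per-subject data frame with `subject_id`, `hiv_status`, and
#'   `combo_cat` (the last-visit combination score); optionally
#'   `last_visit_time`. Subjects with missing `combo_cat` are returned with
#'   group `NA` and counted in the `n_unscored` attribute.
#' @param probs Lower/upper quantile probabilities.
#' @param scope `"cohort"` (cut-points over everyone, default) or
#'   `"hiv_positive"` (cut-points over HIV-positive subjects only).
#' @return Data frame of assignments (`subject_id`, `hiv_status`, `combo_cat`,
#'   `group`) with attributes `cutpoints` and `n_unscored`. Refuses to group
#'   fewer than 10 scored subjects.
#' @export
assign_groups <- function(scores, probs = c(0.20, 0.80),
                          scope = c("cohort", "hiv_positive")) {
  scope <- match.arg(scope)
  stopifnot(all(c("subject_id", "hiv_status", "combo_cat") %in% names(scores)),
            length(probs) == 2, probs[1] < probs[2])
  if (anyDuplicated(scores$subject_id))
    stop("scores must have one row per subject")
  scored <- !is.na(scores$combo_cat)
  if (sum(scored) < 10)
    stop("refusing to assign groups with fewer than 10 scored subjects")
  pool <- if (scope == "cohort") scores$combo_cat[scored] else
    scores$combo_cat[scored & scores$hiv_status == "positive"]
  q <- stats::quantile(pool, probs = probs, type = 7, names = FALSE)
  if (q[1] == q[2])
    warning("degenerate combination scores: both cut-points coincide")
  grp <- rep(NA_character_, nrow(scores))
  neg <- scores$hiv_status == "negative"
  pos <- scores$hiv_status == "positive"
  grp[neg & scored] <- "HIV-negative"
  grp[pos & scored] <- "HIV-positive"
  grp[pos & scored & scores$combo_cat <= q[1]] <- "BottomCATs"
  grp[pos & scored & scores$combo_cat >= q[2]] <- "TopCATs"
  out <- scores
  out$group <- grp
  attr(out, "cutpoints") <- q
  attr(out, "n_unscored") <- sum(!scored)
  out
}

#' Global composite scores per visit
#'
#' Mean of the direction-harmonized component z-scores for each composite:
#' global executive (Cogstate subtests except One Back), global speed (TOVA
#' speed measures plus One Back), and global CAT (gap, HINT composite, digit
#' triplet). A composite with more than `max_missing` of its components
#' missing is set missing.
#'
#' @param cohort Visit-level data frame carrying `z_`-prefixed component
#'   columns (see [apply_norms()]).
#' @param max_missing Largest tolerated fraction of missing components.
#' @param prefix z-column prefix.
#' @return `cohort` with `global_executive`, `global_speed`, `global_cat`
#'   columns added.
#' @export
global_scores <- function(cohort, max_missing = 0.5, prefix = "z_") {
  comp <- composite_components()
  mean_tol <- function(cols) {
    cols <- paste0(prefix, cols)
    missing_cols <- setdiff(cols, names(cohort))
    if (length(missing_cols) > 0)
      stop("missing z-score columns: ", paste(missing_cols, collapse = ", "))
    m <- as.matrix(cohort[cols])
    frac_na <- rowMeans(is.na(m))
    out <- rowMeans(m, na.rm = TRUE)
    out[frac_na > max_missing] <- NA_real_
    out[is.nan(out)] <- NA_real_
    out
  }
  cohort$global_executive <- mean_tol(comp$executive)
  cohort$global_speed <- mean_tol(comp$speed)
  cohort$global_cat <- mean_tol(comp$cat)
  cohort
}
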