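# Synthetic longitudinal cohort generator. Emulates the statistical structure
# the trajectory analysis assumes: four latent classes (HIV-negative,
# HIV-positive, and HIV-positive subgroups with good / poor central auditory
# ability), visits at ~6-month intervals with jitter and dropout, a positive
# learning slope in most classes with a flat-to-declining poor-CAT class,
# age effects, correlated subject random intercepts and slopes, and a latent
# central-auditory ability that links the grouping variable to the class so
# the quantile grouping is recoverable rather than arbitrary. Ground truth is
# persisted alongside every generated cohort.

TRUE_CLASSES <- c("HIV-negative", "HIV-positive", "TopCATs", "BottomCATs")

stream_seed <- function(seed, stream) {
  offsets <- c(demographics = 1L, visits = 2L, outcomes = 3L, listeners = 4L,
               peripheral = 5L)
  if (!stream %in% names(offsets)) stop("unknown stream: ", stream)
  (as.integer(seed) * 31L + offsets[[stream]]) %% 2147483647L
}

#' Per-outcome generative coefficients (defaults)
#'
#' One row per outcome. Trajectories are generated on a latent performance
#' scale (reference-SD units, higher = better) and mapped to natural units by
#' `mean`, `sd` and the outcome's direction. Learning slopes are in SD-units
#' per day: over a 3.5-year horizon the default +4e-4/day amounts to about
#' +0.5 SD of improvement, a visible but not dramatic practice effect. The
#' poor-CAT class is near-flat (slightly negative for MoCA and the three
#' auditory tests, where decline shows most clearly). Random-effect SDs and
#' the residual SD are on the performance scale; `age_beta` is SD-units per
#' year of age.
#'
#' @return Data frame of class `outcome_params`.
#' @export
default_outcome_params <- function() {
  dirs <- outcome_directions()
  o <- names(dirs)
  means <- c(gap_ms = 6.5, hint_snr = -3, tdt_snr = -12, moca = 27,
             tova_rt = 450, tova_exg_mu = 380, tova_acs = 95,
             gml_speed = 0.75, gml_errors = 55, ocl_acc = 0.85,
             onb_rt = 720, cpal_acc = 0.80)
  sds <- c(gap_ms = 2, hint_snr = 1.2, tdt_snr = 2.5, moca = 2.8,
           tova_rt = 60, tova_exg_mu = 55, tova_acs = 15,
           gml_speed = 0.15, gml_errors = 15, ocl_acc = 0.08,
           onb_rt = 90, cpal_acc = 0.10)
  is_cat <- o %in% composite_components()$cat
  slope_bottom <- ifelse(is_cat | o == "moca", -0.5e-4, 1.0e-4)
  out <- data.frame(
    outcome = o,
    direction = unname(dirs[o]),
    mean = unname(means[o]),
    sd = unname(sds[o]),
    slope_hiv_negative = 4.5e-4,
    slope_hiv_positive = 4.0e-4,
    slope_topcats = 4.5e-4,
    slope_bottomcats = slope_bottom,
    age_beta = -0.02,
    re_int_sd = 0.8,
    re_slope_sd = 5e-4,
    re_corr = -0.2,
    resid_sd = 0.45
  )
  class(out) <- c("outcome_params", "data.frame")
  out
}

#' Cohort generator parameters
#'
#' Defaults mirror the demographic shape of a ~380-subject HIV cohort:
#' class sizes 90 / 164 / 53 / 75, class-specific age distributions, visits
#' every ~182 days with jitter over a 1400-day enrolment window (so a few
#' visits fall beyond the 3.5-year analysis horizon and exercise the horizon
#' filter), geometric dropout, and a latent central-auditory ability with a
#' clearly impaired declining class (-2 reference-SD) so the last-visit
#' quantile grouping can recover the class labels.
#'
#' @param n Named class sizes.
#' @param age_mean,age_sd Named per-class age distributions (years).
#' @param age_range Truncation range for ages.
#' @param visit_interval_days Mean interval between visits.
#' @param visit_jitter_sd SD of the Gaussian jitter on each interval (days).
#' @param followup_days Enrolment window; visits beyond it are never
#'   scheduled. Deliberately longer than the 1278-day analysis horizon.
#' @param dropout_hazard Per-visit probability of leaving after any visit.
#' @param cat_class_mean Named latent CAT-ability class means (reference-SD
#'   units).
#' @param cat_within_sd Within-class SD of the shared CAT ability.
#' @param cat_test_sd SD of the stable per-test deviation around the shared
#'   ability.
#' @param pta_mean Named per-class mean audiometric threshold (dB HL).
#' @param p_abnormal_hearing Fraction of subjects given an exclusionary
#'   audiogram or tympanogram.
#' @param p_positive_history Fraction of subjects given a positive history
#'   flag.
#' @param outcomes An [default_outcome_params()] table (subset its rows to
#'   generate fewer outcomes).
#' @param use_cat_simulators If `TRUE`, raw CAT scores come from running the
#'   adaptive-test simulators against per-subject-visit listeners instead of
#'   the direct linear generator.
#' @param listener_slopes Psychometric slopes used when simulating CAT runs
#'   (gap slope per log2-ms, hint per dB, tdt per dB).
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(
    n = c("HIV-negative" = 90, "HIV-positive" = 164,
          "TopCATs" = 53, "BottomCATs" = 75),
    age_mean = c("HIV-negative" = 25.9, "HIV-positive" = 40.8,
                 "TopCATs" = 38.1, "BottomCATs" = 42.1),
    age_sd = c("HIV-negative" = 11.8, "HIV-positive" = 13.6,
               "TopCATs" = 12.8, "BottomCATs" = 8.4),
    age_range = c(18, 70),
    visit_interval_days = 182,
    visit_jitter_sd = 14,
    followup_days = 1400,
    dropout_hazard = 0.04,
    cat_class_mean = c("HIV-negative" = 0, "HIV-positive" = 0,
                       "TopCATs" = 1.2, "BottomCATs" = -2.0),
    cat_within_sd = 0.7,
    cat_test_sd = 0.3,
    pta_mean = c("HIV-negative" = 3.7, "HIV-positive" = 7.0,
                 "TopCATs" = 5.5, "BottomCATs" = 7.9),
    p_abnormal_hearing = 0.03,
    p_positive_history = 0.03,
    outcomes = default_outcome_params(),
    use_cat_simulators = FALSE,
    listener_slopes = c(gap = 4, hint = 1, tdt = 0.8)) {
  stopifnot(all(TRUE_CLASSES %in% names(n)),
            all(n >= 0), dropout_hazard >= 0, dropout_hazard < 1,
            visit_interval_days > 0, followup_days > 0,
            cat_within_sd > 0, cat_test_sd > 0,
            all(outcomes$sd > 0), all(outcomes$resid_sd >= 0))
  structure(as.list(environment()), class = "cohort_params")
}

#' Generate per-subject visit schedules
#'
#' First visit at day 0; each later visit at the previous plus the mean
#' interval plus Gaussian jitter, truncated at the enrolment window; after
#' every visit the subject drops out with the configured hazard. Every
#' subject keeps at least one visit.
#'
#' @param ids Subject identifiers.
#' @param params A [cohort_params()].
#' @param seed Optional seed.
#' @return Data frame `subject_id`, `visit_index`, `visit_time` (days).
#' @export
generate_visits <- function(ids, params = cohort_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(ids, function(id) {
    t <- 0
    times <- 0
    repeat {
      if (params$dropout_hazard > 0 &&
          stats::runif(1) < params$dropout_hazard) break
      jitter <- if (params$visit_jitter_sd > 0)
        stats::rnorm(1, 0, params$visit_jitter_sd) else 0
      t <- t + params$visit_interval_days + jitter
      if (t > params$followup_days) break
      times <- c(times, round(t))
    }
    data.frame(subject_id = id, visit_index = seq_along(times),
               visit_time = times)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

draw_subjects <- function(params, seed) {
  set.seed(seed)
  cls <- rep(TRUE_CLASSES, times = params$n[TRUE_CLASSES])
  n <- length(cls)
  ids <- sprintf("S%04d", seq_len(n))
  age0 <- rtrunc_norm(n, params$age_mean[cls], params$age_sd[cls],
                      params$age_range[1], params$age_range[2])
  cat_ability <- stats::rnorm(n, params$cat_class_mean[cls],
                              params$cat_within_sd)
  data.frame(subject_id = ids, true_class = cls,
             hiv_status = ifelse(cls == "HIV-negative", "negative", "positive"),
             age0 = age0, cat_ability = cat_ability)
}

#' Generate outcome trajectories for scheduled visits
#'
#' Each outcome follows the trajectory-model generative equation on the
#' latent performance scale: class-specific learning slope, age effect,
#' correlated subject random intercept and slope, Gaussian residuals. The
#' three central auditory outcomes share the subject's latent CAT ability as
#' their random intercept (plus a stable per-test deviation), which links the
#' grouping variable to the generating class. Performance maps to natural
#' units via each outcome's mean/SD and direction.
#'
#' @param subjects Data frame from the generator's demographics stage
#'   (`subject_id`, `true_class`, `hiv_status`, `age0`, `cat_ability`).
#' @param visits Data frame from [generate_visits()].
#' @param params A [cohort_params()].
#' @param seed Optional seed.
#' @return List with `cohort` (long visit-level table) and `truth`
#'   (per-subject random effects and the generating coefficient table).
#' @export
generate_outcomes <- function(subjects, visits, params = cohort_params(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  op <- params$outcomes
  long <- merge(visits, subjects, by = "subject_id", sort = FALSE)
  long <- long[order(long$subject_id, long$visit_time), , drop = FALSE]
  ns <- nrow(subjects)
  slope_col <- paste0("slope_", gsub("-", "_", tolower(subjects$true_class)))
  truth_re <- data.frame(subject_id = subjects$subject_id,
                         true_class = subjects$true_class,
                         cat_ability = subjects$cat_ability)
  cat_set <- composite_components()$cat
  for (k in seq_len(nrow(op))) {
    o <- op$outcome[k]
    # correlated (intercept, slope) random effects
    z1 <- stats::rnorm(ns); z2 <- stats::rnorm(ns)
    b1 <- op$re_slope_sd[k] *
      (op$re_corr[k] * z1 + sqrt(1 - op$re_corr[k]^2) * z2)
    if (o %in% cat_set) {
      test_dev <- stats::rnorm(ns, 0, params$cat_test_sd)
      b0 <- subjects$cat_ability + test_dev
    } else {
      b0 <- op$re_int_sd[k] * z1
    }
    slopes <- as.numeric(op[k, ][slope_col])
    idx <- match(long$subject_id, subjects$subject_id)
    t <- long$visit_time
    perf <- b0[idx] + (slopes[idx] + b1[idx]) * t +
      op$age_beta[k] * (subjects$age0[idx] - 40) / 1 +
      stats::rnorm(nrow(long), 0, op$resid_sd[k])
    sign <- if (op$direction[k] == "higher_better") 1 else -1
    long[[o]] <- op$mean[k] + op$sd[k] * sign * perf
    truth_re[[paste0("b0_", o)]] <- b0
    truth_re[[paste0("b1_", o)]] <- b1
  }
  long$age_at_visit <- long$age0 + long$visit_time / 365.25
  cohort <- long[c("subject_id", "hiv_status", "visit_index", "visit_time",
                   "age_at_visit", op$outcome)]
  rownames(cohort) <- NULL
  list(cohort = cohort,
       truth = list(subjects = truth_re, coefficients = op))
}

draw_peripheral <- function(subjects, visits, params, seed) {
  set.seed(seed)
  long <- merge(visits, subjects[c("subject_id", "true_class")],
                by = "subject_id", sort = FALSE)
  long <- long[order(long$subject_id, long$visit_time), , drop = FALSE]
  n <- nrow(long)
  pta <- params$pta_mean[long$true_class]
  aud_cols <- cohort_columns()$audiogram
  for (cn in aud_cols)
    long[[cn]] <- pmin(pmax(2 * round(stats::rnorm(n, pta, 5) / 2), -10), 24)
  long$tymp_type <- "A"
  long$tymp_pressure <- round(rtrunc_norm(n, -20, 25, -95, 45))
  long$tymp_admittance <- round(rtrunc_norm(n, 0.9, 0.25, 0.35, 1.65), 2)
  for (cn in cohort_columns()$history) long[[cn]] <- FALSE

  ids <- unique(long$subject_id)
  bad_hear <- ids[stats::runif(length(ids)) < params$p_abnormal_hearing]
  for (id in bad_hear) {
    rows <- which(long$subject_id == id)
    r <- sample(rows, 1)
    if (stats::runif(1) < 0.5) {
      long[[sample(aud_cols, 1)]][r] <- sample(30:60, 1)
    } else {
      long$tymp_type[r] <- sample(c("B", "C"), 1)
    }
  }
  remaining <- setdiff(ids, bad_hear)
  bad_hx <- remaining[stats::runif(length(remaining)) < params$p_positive_history]
  hx_cols <- cohort_columns()$history
  for (id in bad_hx)
    long[[sample(hx_cols, 1)]][long$subject_id == id] <- TRUE
  long[c("subject_id", "visit_time", aud_cols, "tymp_type", "tymp_pressure",
         "tymp_admittance", hx_cols)]
}

#' Generate raw CAT scores by running the adaptive-test simulators
#'
#' For each subject-visit, per-test listener thresholds are derived from the
#' subject's latent natural-scale CAT trajectory and the three procedures are
#' run: the gap staircase, the three HINT noise conditions plus composite
#' (noise-front is made harder and the lateral conditions easier by a fixed
#' spatial-release offset, so their mean equals the latent composite), and
#' the digit-triplet test. Non-converged tracks yield missing scores.
#'
#' @param cohort Visit-level table carrying `subject_id`, `visit_time` and
#'   latent `gap_ms`, `hint_snr`, `tdt_snr` columns (the direct simulation,
#'   used as listener thresholds).
#' @param params A [cohort_params()].
#' @param seed Optional seed.
#' @return Data frame `subject_id`, `visit_time`, `gap_ms`, `hint_front`,
#'   `hint_right`, `hint_left`, `hint_snr`, `tdt_snr`.
#' @export
generate_cat_raw <- function(cohort, params = cohort_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sl <- params$listener_slopes
  gcfg <- gap_config()
  hcfg <- hint_config()
  tcfg <- tdt_config()
  res <- lapply(seq_len(nrow(cohort)), function(i) {
    gap_thr <- max(cohort$gap_ms[i], gcfg$min_gap * 1.5)
    gl <- gap_listener(gap_thr, slope = sl[["gap"]])
    gt <- run_gap_staircase(gl, gcfg)
    h <- cohort$hint_snr[i]
    offs <- c(front = 2, right = -1, left = -1)
    hsrt <- vapply(names(offs), function(cond) {
      hl <- psychometric_listener(h + offs[[cond]], slope = sl[["hint"]])
      run_hint_condition(hl, hcfg, paste0("noise_", cond))$estimate
    }, numeric(1))
    tl <- psychometric_listener(cohort$tdt_snr[i], slope = sl[["tdt"]],
                                guess_rate = 0.1)
    tt <- run_tdt(tl, tcfg)
    data.frame(subject_id = cohort$subject_id[i],
               visit_time = cohort$visit_time[i],
               gap_ms = gt$estimate,
               hint_front = hsrt[["front"]], hint_right = hsrt[["right"]],
               hint_left = hsrt[["left"]],
               hint_snr = hint_composite(hsrt[["front"]], hsrt[["right"]],
                                         hsrt[["left"]]),
               tdt_snr = tt$estimate)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates the demographics, visit-schedule, outcome, and peripheral
#' streams from a single master seed split into named sub-streams, so each
#' component is reproducible on its own. When `params$use_cat_simulators` is
#' `TRUE`, the three CAT columns are replaced by scores measured by the
#' adaptive-test simulators (the direct columns are kept as `latent_*`).
#'
#' @param params A [cohort_params()].
#' @param seed Master integer seed.
#' @return List with `cohort` (visit-level table including audiogram,
#'   tympanometry and history columns), `truth`, and `params`.
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1) {
  subjects <- draw_subjects(params, stream_seed(seed, "demographics"))
  visits <- generate_visits(subjects$subject_id, params,
                            stream_seed(seed, "visits"))
  gen <- generate_outcomes(subjects, visits, params,
                           stream_seed(seed, "outcomes"))
  periph <- draw_peripheral(subjects, visits, params,
                            stream_seed(seed, "peripheral"))
  cohort <- merge(gen$cohort, periph, by = c("subject_id", "visit_time"),
                  sort = FALSE)
  cohort <- cohort[order(cohort$subject_id, cohort$visit_time), , drop = FALSE]
  if (isTRUE(params$use_cat_simulators) &&
      all(composite_components()$cat %in% names(cohort))) {
    raw <- generate_cat_raw(cohort, params, stream_seed(seed, "listeners"))
    for (v in composite_components()$cat)
      cohort[[paste0("latent_", v)]] <- cohort[[v]]
    key <- paste(cohort$subject_id, cohort$visit_time)
    rkey <- paste(raw$subject_id, raw$visit_time)
    m <- match(key, rkey)
    cohort$gap_ms <- raw$gap_ms[m]
    cohort$hint_snr <- raw$hint_snr[m]
    cohort$tdt_snr <- raw$tdt_snr[m]
  }
  rownames(cohort) <- NULL
  list(cohort = cohort, truth = gen$truth, params = params)
}

#' Age at each subject's last retained visit
#'
#' The trajectory models use age at last visit as a subject-constant
#' covariate; compute it after filtering so "last" refers to the analysis
#' sample.
#'
#' @param cohort Visit-level data frame with `subject_id`, `visit_time`,
#'   `age_at_visit`.
#' @return `cohort` with an `age_at_last_visit` column.
#' @export
add_age_at_last_visit <- function(cohort) {
  last <- last_visit_rows(cohort)
  cohort$age_at_last_visit <-
    last$age_at_visit[match(cohort$subject_id, last$subject_id)]
  cohort
}

#' Run the full measurement-and-inference chain on a synthetic cohort
#'
#' generate -> filter -> norm/z-score -> combination CAT score -> last-visit
#' quantile grouping -> global composites -> per-outcome linear mixed-effects
#' trajectory fits -> report table.
#'
#' @param params A [cohort_params()].
#' @param seed Master seed.
#' @param fit_outcomes Outcome columns to model; defaults to every generated
#'   outcome plus the three global composites.
#' @return List: `cohort` (scored, grouped visit table), `audit`, `norms`,
#'   `groups`, `fits`, `report`, `truth`.
#' @export
run_pipeline <- function(params = cohort_params(), seed = 1,
                         fit_outcomes = NULL) {
  gen <- generate_cohort(params, seed)
  filt <- apply_filters(gen$cohort)
  cohort <- add_age_at_last_visit(filt$cohort)
  norms <- build_norms(cohort)
  scored <- apply_norms(cohort, norms)
  last <- last_visit_rows(scored)
  combo <- data.frame(
    subject_id = last$subject_id,
    hiv_status = last$hiv_status,
    combo_cat = combination_cat_score(last$z_gap_ms, last$z_hint_snr,
                                      last$z_tdt_snr),
    last_visit_time = last$visit_time
  )
  groups <- assign_groups(combo)
  scored$group <- groups$group[match(scored$subject_id, groups$subject_id)]
  scored <- global_scores(scored)
  if (is.null(fit_outcomes))
    fit_outcomes <- c(intersect(gen$params$outcomes$outcome, names(scored)),
                      "global_executive", "global_speed", "global_cat")
  usable <- scored[!is.na(scored$group), , drop = FALSE]
  fits <- lapply(fit_outcomes, function(o)
    tryCatch(fit_trajectory(usable, o), error = function(e) NULL))
  names(fits) <- fit_outcomes
  report <- build_report(fits[!vapply(fits, is.null, logical(1))])
  list(cohort = scored, audit = filt$audit, norms = norms, groups = groups,
       fits = fits, report = report, truth = gen$truth)
}
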