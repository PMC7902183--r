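# Programmatic fixtures shared across tests.

# Six-subject cohort exercising every selection rule exactly once:
#   F1: four visits, one beyond the 3.5-year horizon -> truncation leaves 3
#   F2: only three visits
#   F3: one audiometric threshold of 30 dB HL
#   F4: positive concussion history
#   F5, F6: clean, retained
filter_demo_cohort <- function() {
  base_visit <- function(id, status, times, age0 = 35) {
    n <- length(times)
    df <- data.frame(
      subject_id = id, hiv_status = status, visit_time = times,
      age_at_visit = age0 + times / 365.25,
      aud_r_500 = 10, aud_r_1000 = 10, aud_r_2000 = 10, aud_r_4000 = 10,
      aud_l_500 = 8, aud_l_1000 = 8, aud_l_2000 = 12, aud_l_4000 = 12,
      tymp_type = "A", tymp_pressure = -20, tymp_admittance = 0.9,
      hx_ear_drainage = FALSE, hx_concussion = FALSE,
      hx_noise_chemical = FALSE, hx_neuro_disease = FALSE,
      hx_mental_illness = FALSE, hx_ototoxic = FALSE,
      hx_chemotherapy = FALSE
    )
    df
  }
  f1 <- base_visit("F1", "positive", c(0, 182, 364, 1300))
  f2 <- base_visit("F2", "positive", c(0, 182, 364))
  f3 <- base_visit("F3", "negative", c(0, 182, 364, 546))
  f3$aud_r_2000[2] <- 30
  f4 <- base_visit("F4", "positive", c(0, 182, 364, 546))
  f4$hx_concussion <- TRUE
  f5 <- base_visit("F5", "negative", c(0, 180, 370, 550))
  f6 <- base_visit("F6", "positive", c(0, 185, 360, 545))
  rbind(f1, f2, f3, f4, f5, f6)
}

# Small synthetic scored cohort (no trajectory structure) for norm and
# grouping tests.
scoring_fixture <- function(seed = 123, n_neg = 20, n_pos = 40) {
  set.seed(seed)
  ids <- c(sprintf("N%02d", 1:n_neg), sprintf("P%02d", 1:n_pos))
  status <- rep(c("negative", "positive"), c(n_neg, n_pos))
  rows <- lapply(seq_along(ids), function(i) {
    data.frame(subject_id = ids[i], hiv_status = status[i],
               visit_time = c(0, 182, 364, 546),
               gap_ms = rnorm(4, 6.5, 2), hint_snr = rnorm(4, -3, 1.2),
               tdt_snr = rnorm(4, -12, 2.5), moca = rnorm(4, 27, 2.8),
               tova_rt = rnorm(4, 450, 60), tova_exg_mu = rnorm(4, 380, 55),
               tova_acs = rnorm(4, 95, 15), gml_speed = rnorm(4, 0.75, 0.15),
               gml_errors = rnorm(4, 55, 15), ocl_acc = rnorm(4, 0.85, 0.08),
               onb_rt = rnorm(4, 720, 90), cpal_acc = rnorm(4, 0.8, 0.1))
  })
  do.call(rbind, rows)
}

# Small noiseless trajectory dataset from known coefficients: three groups,
# no random effects, zero residual noise.
noiseless_trajectory_data <- function() {
  groups <- c("HIV-positive", "TopCATs", "BottomCATs")
  beta <- list(int = 10, g = c("HIV-positive" = 0, "TopCATs" = 1,
                               "BottomCATs" = -1),
               age = 0.05,
               t = 2.0,          # per year
               tg = c("HIV-positive" = 0, "TopCATs" = 0.5,
                      "BottomCATs" = -1.5),
               ag = c("HIV-positive" = 0, "TopCATs" = -0.02,
                      "BottomCATs" = 0.03))
  rows <- list()
  sid <- 0
  for (g in groups) {
    for (s in 1:6) {
      sid <- sid + 1
      age <- 30 + 2 * sid
      times <- c(0, 180, 360, 540)
      y <- beta$int + beta$g[[g]] + beta$age * age +
        (beta$t + beta$tg[[g]]) * times / 365.25 +
        beta$ag[[g]] * age
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sprintf("N%02d", sid), group = g,
        age_at_last_visit = age, visit_time = times, y = y)
    }
  }
  list(data = do.call(rbind, rows), beta = beta)
}

# Reduced-size generator parameters for mixed-model calibration replicates:
# a single outcome, no dropout, no filter violators, ~90 subjects over 7
# visits.
calibration_params <- function(delta_perf_per_day = 0) {
  op <- default_outcome_params()
  op <- op[op$outcome == "moca", , drop = FALSE]
  op$slope_bottomcats <- op$slope_hiv_positive + delta_perf_per_day
  cohort_params(
    n = c("HIV-negative" = 15, "HIV-positive" = 40,
          "TopCATs" = 10, "BottomCATs" = 25),
    outcomes = op,
    dropout_hazard = 0,
    p_abnormal_hearing = 0,
    p_positive_history = 0,
    followup_days = 1100
  )
}

# Generate one calibration cohort and fit the trajectory model with the true
# class labels as groups (isolates the inference machinery from grouping).
calibration_fit <- function(seed, delta_perf_per_day = 0) {
  p <- calibration_params(delta_perf_per_day)
  g <- generate_cohort(p, seed)
  d <- g$cohort
  d$group <- g$truth$subjects$true_class[
    match(d$subject_id, g$truth$subjects$subject_id)]
  d <- add_age_at_last_visit(d)
  fit_trajectory(d, "moca")
}

# Natural-units interaction implied by a performance-scale slope difference.
moca_natural_delta <- function(delta_perf_per_day) {
  op <- default_outcome_params()
  op$sd[op$outcome == "moca"] * delta_perf_per_day
}
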