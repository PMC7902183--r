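test_that("noiseless data with no random effects is recovered exactly", {
  fx <- noiseless_trajectory_data()
  fit <- fit_trajectory(fx$data, "y")
  expect_true(fit$converged)
  s <- fit$slopes
  # per-group slopes in units/day equal the generating per-year slopes / 365.25
  expect_equal(s$slope_per_day[s$group == "HIV-positive"],
               fx$beta$t / 365.25, tolerance = 1e-6)
  expect_equal(s$slope_per_day[s$group == "TopCATs"],
               (fx$beta$t + fx$beta$tg[["TopCATs"]]) / 365.25,
               tolerance = 1e-6)
  expect_equal(s$slope_per_day[s$group == "BottomCATs"],
               (fx$beta$t + fx$beta$tg[["BottomCATs"]]) / 365.25,
               tolerance = 1e-6)
  ti <- test_interaction(fit, "time_group", "BottomCATs")
  expect_equal(ti$estimate, fx$beta$tg[["BottomCATs"]] / 365.25,
               tolerance = 1e-6)
  ai <- test_interaction(fit, "age_group", "TopCATs")
  expect_equal(ai$estimate, fx$beta$ag[["TopCATs"]], tolerance = 1e-6)
})

test_that("reference slope + interaction reconstructs each group slope", {
  set.seed(501)
  fit <- calibration_fit(501, delta_perf_per_day = -3e-4)
  s <- fit$slopes
  ref <- s$slope_per_day[s$group == fit$reference_group]
  for (g in setdiff(s$group, fit$reference_group)) {
    ti <- test_interaction(fit, "time_group", g)
    expect_equal(s$slope_per_day[s$group == g], ref + ti$estimate,
                 tolerance = 1e-10)
  }
})

test_that("interaction queries enforce their contract", {
  fit <- calibration_fit(7)
  expect_error(test_interaction(fit, "time_group", "HIV-positive"),
               "reference")
  expect_error(test_interaction(fit, "time_group", "NoSuchGroup"), "unknown")
  row <- test_interaction(fit, "age_group", "BottomCATs")
  expect_true(all(c("estimate", "se", "z", "p") %in% names(row)))
  expect_true(row$p >= 0 && row$p <= 1)
})

test_that("clusters without replication fall back to the OLS solution", {
  # one visit per subject: no within-subject information, so the mixed model
  # must agree with closed-form least squares on the fixed-effect design
  set.seed(20)
  n <- 120
  d <- data.frame(
    subject_id = sprintf("U%03d", 1:n),
    group = sample(c("HIV-positive", "TopCATs", "BottomCATs"), n, TRUE),
    age_at_last_visit = runif(n, 25, 60),
    visit_time = sample(0:1200, n, TRUE))
  d$y <- 5 + 0.1 * d$age_at_last_visit + 0.002 * d$visit_time +
    ifelse(d$group == "BottomCATs", -0.001, 0) * d$visit_time + rnorm(n, 0, 1)
  fit <- suppressWarnings(
    fit_trajectory(d, "y", random = "intercept"))
  g <- factor(d$group, levels = c("HIV-positive", "BottomCATs", "TopCATs"))
  X <- model.matrix(~ g + age_at_last_visit + I(visit_time / 365.25) +
                      I(visit_time / 365.25):g + age_at_last_visit:g, data = d)
  beta_ols <- solve(crossprod(X), crossprod(X, d$y))
  got <- fit$fixef$estimate[fit$fixef$term == "t_yr"]
  expect_equal(got, beta_ols[rownames(beta_ols) == "I(visit_time/365.25)"][[1]],
               tolerance = 1e-4)
})

test_that("a singular random-slope fit degrades to intercept-only", {
  # no slope variance in truth and few subjects: the 2x2 covariance is
  # frequently singular; the refit must be flagged but still usable
  set.seed(88)
  found_singular <- FALSE
  for (seed in 1:5) {
    op <- default_outcome_params()
    op <- op[op$outcome == "moca", , drop = FALSE]
    op$re_slope_sd <- 1e-12
    p <- cohort_params(n = c("HIV-negative" = 6, "HIV-positive" = 10,
                             "TopCATs" = 4, "BottomCATs" = 6),
                       outcomes = op, dropout_hazard = 0,
                       p_abnormal_hearing = 0, p_positive_history = 0)
    g <- generate_cohort(p, seed)
    d <- g$cohort
    d$group <- g$truth$subjects$true_class[
      match(d$subject_id, g$truth$subjects$subject_id)]
    d <- add_age_at_last_visit(d)
    fit <- suppressWarnings(fit_trajectory(d, "moca"))
    expect_true(fit$converged)
    if (fit$singular) {
      found_singular <- TRUE
      expect_equal(fit$random_structure, "intercept")
    }
  }
  expect_true(found_singular)
})

test_that("the report table mirrors the study layout and round-trips", {
  fits <- list(moca = calibration_fit(31), moca_again = calibration_fit(32))
  rep1 <- build_report(fits)
  expect_equal(nrow(rep1), 2)
  expect_identical(rep1$p_age_ref, c("Ref", "Ref"))
  expect_identical(rep1$p_time_ref, c("Ref", "Ref"))
  expect_true(all(c("slope_ref_e4", "slope_topcats_e4", "slope_bottomcats_e4",
                    "p_time_topcats", "p_time_bottomcats",
                    "p_time_bottomcats_bh_extension") %in% names(rep1)))
  # slopes are reported in 1e-4 units/day
  f <- fits$moca
  expect_equal(rep1$slope_ref_e4[1],
               1e4 * f$slopes$slope_per_day[f$slopes$group == "HIV-positive"])
  # CSV round-trip preserves the table
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rep1, tmp, row.names = FALSE)
  back <- utils::read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back$slope_bottomcats_e4, rep1$slope_bottomcats_e4,
               tolerance = 1e-12)
  expect_identical(back$p_time_ref, rep1$p_time_ref)

  # a missing fit yields a flagged row
  rep2 <- build_report(list(good = calibration_fit(33), bad = NULL))
  expect_false(rep2$converged[rep2$outcome == "bad"])
})

test_that("the fitted likelihood is no worse than the generating parameters", {
  # optimizer sanity: evaluate the lmer deviance at the fitted optimum vs
  # the truth-implied parameters on a few replicates
  for (seed in 41:43) {
    fit <- calibration_fit(seed)
    m <- fit$model
    dev_fun <- lme4::lmer(formula(m), data = model.frame(m), REML = FALSE,
                          devFunOnly = TRUE)
    opt_theta <- lme4::getME(m, "theta")
    ml_fit <- suppressWarnings(lme4::refitML(m))
    dev_at_opt <- dev_fun(lme4::getME(ml_fit, "theta"))
    # truth: RE sds from the generator, scaled by residual sd
    op <- default_outcome_params(); op <- op[op$outcome == "moca", ]
    sd_nat <- op$sd
    resid_sd <- op$resid_sd * sd_nat
    sd0 <- op$re_int_sd * sd_nat
    sd1 <- op$re_slope_sd * sd_nat * 365.25 # slope RE acts on time in years
    th_true <- c(sd0, op$re_corr * sd1, sqrt(1 - op$re_corr^2) * sd1) /
      resid_sd
    dev_at_truth <- dev_fun(th_true)
    expect_lte(dev_at_opt, dev_at_truth + 1e-6)
  }
})
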