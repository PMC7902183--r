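# Linear mixed-effects trajectory analysis. For one outcome y:
#   y_ij = b0 + b_g group_i + b_a age_i + b_t t_ij
#          + b_tg (t_ij x group_i) + b_ag (age_i x group_i)
#          + u0_i + u1_i t_ij + e_ij
# with (u0, u1) zero-mean bivariate normal with free covariance, fit by
# lme4::lmer. Time is continuous days from each subject's first visit
# (internally rescaled to years for a well-conditioned optimization, with all
# reported slopes converted back to per-day units). Inference is large-sample
# Wald z. The reference group's slope is b_t; every other group's slope is
# b_t plus its time-by-group interaction.

#' Fit a linear mixed-effects trajectory model for one outcome
#'
#' @param data Visit-level data frame with the outcome column, `group`
#'   (fixed per subject), an age column (age at last visit, constant within
#'   subject), a time column in days from first visit, and a subject id.
#' @param outcome Name of the outcome column.
#' @param reference_group Reference level for the group factor (default
#'   `"HIV-positive"`).
#' @param time,age,subject,group Column names.
#' @param method `"REML"` (default) or `"ML"`.
#' @param random `"intercept_slope"` (default; per-subject intercept and time
#'   slope with free covariance) or `"intercept"`. A singular
#'   intercept-plus-slope fit is automatically refit intercept-only and
#'   flagged. If lme4 cannot fit at all (e.g. degenerate zero-noise input),
#'   the model falls back to ordinary least squares on the same fixed-effect
#'   design, flagged `random_structure = "none"`.
#' @return A `trajectory_fit` object: lists `slopes` (per-group time slope in
#'   outcome units/day with SE), `interactions` (time-by-group and
#'   age-by-group contrasts vs the reference with Wald z p-values), `fixef`
#'   table, random-effect variances, convergence/singularity flags, and
#'   counts.
#' @export
fit_trajectory <- function(data, outcome, reference_group = "HIV-positive",
                           time = "visit_time", age = "age_at_last_visit",
                           subject = "subject_id", group = "group",
                           method = c("REML", "ML"),
                           random = c("intercept_slope", "intercept")) {
  method <- match.arg(method)
  random <- match.arg(random)
  need <- c(outcome, time, age, subject, group)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0)
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  d <- data.frame(
    y = data[[outcome]],
    t_yr = data[[time]] / 365.25,
    age = data[[age]],
    subject = as.character(data[[subject]]),
    group = as.character(data[[group]])
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (!reference_group %in% d$group)
    stop("reference group '", reference_group, "' absent from data")
  gfix <- tapply(d$group, d$subject, function(g) length(unique(g)))
  if (any(gfix > 1)) stop("group labels must be fixed within subject")
  nv <- table(d$subject)
  if (any(nv < 2))
    warning(sum(nv < 2), " subject(s) contribute a single visit")
  lev <- c(reference_group, sort(setdiff(unique(d$group), reference_group)))
  d$group <- factor(d$group, levels = lev)

  fits <- fit_lmm(d, method, random)
  beta <- fits$beta; V <- fits$V
  groups_other <- lev[-1]

  slope_row <- function(g) {
    cn <- names(beta)
    w <- stats::setNames(numeric(length(beta)), cn)
    w["t_yr"] <- 1
    if (g != reference_group) {
      nm <- paste0("t_yr:group", g)
      if (!nm %in% cn) nm <- paste0("group", g, ":t_yr")
      w[nm] <- 1
    }
    est <- sum(w * beta)
    se <- sqrt(drop(t(w) %*% V %*% w))
    data.frame(group = g, slope_per_day = est / 365.25,
               se_per_day = se / 365.25)
  }
  slopes <- do.call(rbind, lapply(lev, slope_row))
  rownames(slopes) <- NULL

  inter_row <- function(term, g) {
    nm <- if (term == "time_group") paste0("t_yr:group", g) else
      paste0("group", g, ":age")
    if (!nm %in% names(beta)) {
      alt <- if (term == "time_group") paste0("group", g, ":t_yr") else
        paste0("age:group", g)
      nm <- alt
    }
    est <- beta[[nm]]
    se <- sqrt(V[nm, nm])
    z <- est / se
    scale <- if (term == "time_group") 365.25 else 1
    data.frame(term = term, group = g, estimate = est / scale,
               se = se / scale, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  }
  interactions <- do.call(rbind, c(
    lapply(groups_other, function(g) inter_row("time_group", g)),
    lapply(groups_other, function(g) inter_row("age_group", g))
  ))
  rownames(interactions) <- NULL

  structure(list(
    outcome = outcome,
    reference_group = reference_group,
    slopes = slopes,
    interactions = interactions,
    fixef = data.frame(term = names(beta), estimate = unname(beta),
                       se = sqrt(diag(V))),
    varcor = fits$varcor,
    random_structure = fits$random_structure,
    singular = fits$singular,
    converged = fits$converged,
    method = method,
    n_subjects = length(unique(d$subject)),
    n_obs = nrow(d),
    model = fits$model
  ), class = "trajectory_fit")
}

# Internal: try lmer with the requested random structure, degrade gracefully.
fit_lmm <- function(d, method, random) {
  reml <- method == "REML"
  forms <- list(
    intercept_slope = y ~ group + age + t_yr + t_yr:group + age:group +
      (1 + t_yr | subject),
    intercept = y ~ group + age + t_yr + t_yr:group + age:group +
      (1 | subject)
  )
  try_fit <- function(structure_name) {
    tryCatch({
      m <- suppressWarnings(suppressMessages(
        lme4::lmer(forms[[structure_name]], data = d, REML = reml,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     check.nobs.vs.nRE = "ignore",
                     check.nobs.vs.nlev = "ignore"))))
      list(model = m, ok = TRUE)
    }, error = function(e) list(model = NULL, ok = FALSE))
  }
  singular <- FALSE
  structure_used <- random
  f <- try_fit(random)
  if (f$ok && random == "intercept_slope" &&
      suppressWarnings(lme4::isSingular(f$model, tol = 1e-4))) {
    singular <- TRUE
    f2 <- try_fit("intercept")
    if (f2$ok) { f <- f2; structure_used <- "intercept" }
  }
  if (f$ok) {
    m <- f$model
    beta <- lme4::fixef(m)
    V <- as.matrix(stats::vcov(m))
    dimnames(V) <- list(names(beta), names(beta))
    vc <- as.data.frame(lme4::VarCorr(m))
    return(list(beta = beta, V = V, varcor = vc, model = m,
                singular = singular, converged = TRUE,
                random_structure = structure_used))
  }
  # degenerate fallback: ordinary least squares, no random effects
  m <- stats::lm(y ~ group + age + t_yr + t_yr:group + age:group, data = d)
  beta <- stats::coef(m)
  names(beta)[names(beta) == "(Intercept)"] <- "(Intercept)"
  V <- stats::vcov(m)
  if (any(!is.finite(V))) V[!is.finite(V)] <- 0
  list(beta = beta, V = as.matrix(V), varcor = NULL, model = m,
       singular = TRUE, converged = TRUE, random_structure = "none")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> outcome '%s': %d subjects, %d observations\n",
              x$outcome, x$n_subjects, x$n_obs))
  cat(sprintf("  random effects: %s%s | estimation: %s\n",
              x$random_structure, if (x$singular) " (singular refit)" else "",
              x$method))
  cat("  per-group time slopes (units/day):\n")
  s <- x$slopes
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-14s %+.3e (se %.2e)%s\n", s$group[i],
                s$slope_per_day[i], s$se_per_day[i],
                if (s$group[i] == x$reference_group) "  [Ref]" else ""))
  invisible(x)
}

#' Wald test of a group contrast against the reference
#'
#' @param fit A [fit_trajectory()] result.
#' @param term `"time_group"` or `"age_group"`.
#' @param group A non-reference group label.
#' @return One-row data frame with `estimate` (units/day for the time
#'   interaction), `se`, `z`, `p`.
#' @export
test_interaction <- function(fit, term = c("time_group", "age_group"), group) {
  stopifnot(inherits(fit, "trajectory_fit"))
  term <- match.arg(term)
  if (!fit$converged) stop("fit did not converge; no interaction tests")
  if (group == fit$reference_group)
    stop("'", group, "' is the reference group; no contrast against itself")
  row <- fit$interactions[fit$interactions$term == term &
                            fit$interactions$group == group, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown group: ", group)
  rownames(row) <- NULL
  row
}

#' Assemble the trajectory report table across outcomes
#'
#' One row per outcome: per-group time slopes in 1e-4 outcome-units/day, and
#' the age-by-group and time-by-group p-values against the reference group
#' (whose columns carry the literal label `"Ref"`). A Benjamini-Hochberg
#' adjusted column for the Bottom time contrast is appended as a clearly
#' labelled extension beyond the per-outcome reporting convention.
#'
#' @param fits Named list of [fit_trajectory()] results (names are outcome
#'   labels; unnamed lists use each fit's own `outcome`).
#' @param groups Non-reference groups to report (default TopCATs and
#'   BottomCATs, mirroring the headline comparisons; HIV-negative stays in
#'   the model but out of the report).
#' @return Data frame of class `trajectory_report`.
#' @export
build_report <- function(fits, groups = c("TopCATs", "BottomCATs")) {
  stopifnot(length(fits) > 0)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, function(f) f$outcome, character(1))
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is.null(f) || !inherits(f, "trajectory_fit") || !f$converged) {
      out <- data.frame(outcome = nm, converged = FALSE,
                        slope_ref_e4 = NA_real_)
      for (g in groups) {
        out[[paste0("slope_", slug(g), "_e4")]] <- NA_real_
        out[[paste0("p_age_", slug(g))]] <- NA_real_
        out[[paste0("p_time_", slug(g))]] <- NA_real_
      }
      out$p_age_ref <- "Ref"; out$p_time_ref <- "Ref"
      return(out)
    }
    s <- f$slopes
    out <- data.frame(
      outcome = nm, converged = TRUE,
      slope_ref_e4 = 1e4 * s$slope_per_day[s$group == f$reference_group])
    for (g in groups) {
      out[[paste0("slope_", slug(g), "_e4")]] <-
        if (g %in% s$group) 1e4 * s$slope_per_day[s$group == g] else NA_real_
      out[[paste0("p_age_", slug(g))]] <-
        if (g %in% s$group) test_interaction(f, "age_group", g)$p else NA_real_
      out[[paste0("p_time_", slug(g))]] <-
        if (g %in% s$group) test_interaction(f, "time_group", g)$p else NA_real_
    }
    out$p_age_ref <- "Ref"
    out$p_time_ref <- "Ref"
    out
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  bottom_p <- report[[paste0("p_time_", slug("BottomCATs"))]]
  if (!is.null(bottom_p))
    report$p_time_bottomcats_bh_extension <- stats::p.adjust(bottom_p, "BH")
  class(report) <- c("trajectory_report", "data.frame")
  report
}

slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))
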