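# Adaptive psychophysical procedures. Each run_* function plays a virtual
# listener through a trial-by-trial adaptive rule and returns an `aud_track`:
# the ordered trial records plus the threshold estimate the procedure defines.
# All presented levels are quantized to a 0.1-unit grid so that independent
# trial-by-trial traces can be compared bit-for-bit.

q01 <- function(x) round(x * 10) / 10

new_track <- function(test, condition, trials, estimate, estimator_rule,
                      converged) {
  structure(
    list(test = test, condition = condition, trials = trials,
         estimate = estimate, estimator_rule = estimator_rule,
         converged = converged),
    class = "aud_track"
  )
}

#' @export
print.aud_track <- function(x, ...) {
  cat(sprintf("<aud_track> %s%s: %d trials, estimate %s (%s)%s\n",
              x$test,
              if (is.na(x$condition) || x$condition == "none") "" else
                paste0(" [", x$condition, "]"),
              nrow(x$trials),
              if (is.na(x$estimate)) "NA" else format(x$estimate),
              x$estimator_rule,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
as.data.frame.aud_track <- function(x, ...) {
  df <- x$trials
  df$test <- x$test
  df$condition <- x$condition
  df$estimate <- x$estimate
  df
}

trial_df <- function(n) {
  data.frame(index = integer(n), level = numeric(n), response = numeric(n),
             is_reversal = logical(n), phase = character(n))
}

#' Configuration for Bekesy-like pure-tone threshold tracking
#'
#' Discrete-trial analogue of button-press tracking audiometry with pulsed
#' tones (250 ms duration, 20 ms rise/fall, 500 ms interstimulus interval in
#' the hardware this emulates; retained here as metadata). While the tone is
#' heard the level descends, in `big_step` (4 dB) steps until the first
#' reversal and in `small_step` (2 dB) steps thereafter; while unheard it
#' ascends in `small_step` steps. Tracking stops after `reversals_required`
#' good reversals.
#'
#' @param start_level Starting tone level, dB HL.
#' @param big_step Initial descending step, dB.
#' @param small_step Step after the first reversal (and all ascending steps), dB.
#' @param reversals_required Number of good reversals (reversals after the
#'   first direction change) used for the estimate.
#' @param floor_level,ceiling_level Clamp limits for the presented level, dB HL.
#' @param max_trials Trial cap before the track is flagged non-converged.
#' @param tone_duration_ms,rise_fall_ms,isi_ms Stimulus timing metadata.
#' @return A list of class `bekesy_config`.
#' @export
bekesy_config <- function(start_level = 40, big_step = 4, small_step = 2,
                          reversals_required = 6, floor_level = -10,
                          ceiling_level = 110, max_trials = 400,
                          tone_duration_ms = 250, rise_fall_ms = 20,
                          isi_ms = 500) {
  stopifnot(big_step > small_step, small_step > 0, reversals_required >= 2,
            floor_level < ceiling_level, max_trials > 0)
  structure(as.list(environment()), class = "bekesy_config")
}

#' Run a Bekesy-like pure-tone tracking procedure
#'
#' The good reversals are all reversals after the first direction change (the
#' first reversal ends the large-step descent and is excluded). The threshold
#' estimate is the mean level at the good reversals, rounded to the 0.1 dB
#' grid. A track that hits the trial cap, or sits pinned at the floor or
#' ceiling for 10 consecutive trials, is flagged non-converged (estimate `NA`).
#'
#' @param listener An [psychometric_listener()]; a correct response means the
#'   tone was heard (button pressed).
#' @param config A [bekesy_config()].
#' @param seed Optional integer seed applied before the run.
#' @return An `aud_track` with trial records and the threshold estimate (dB HL).
#' @export
run_bekesy <- function(listener, config = bekesy_config(), seed = NULL) {
  stopifnot(inherits(config, "bekesy_config"))
  if (!is.null(seed)) set.seed(seed)
  level <- q01(config$start_level)
  levels <- numeric(0); heard <- logical(0); rev_flag <- logical(0)
  dir_prev <- NA_integer_
  n_rev <- 0L
  had_first_rev <- FALSE
  rev_levels <- numeric(0)
  pinned <- 0L
  converged <- FALSE
  for (i in seq_len(config$max_trials)) {
    h <- respond(listener, level)
    dir <- if (h) -1L else 1L
    is_rev <- !is.na(dir_prev) && dir != dir_prev
    levels <- c(levels, level); heard <- c(heard, h)
    rev_flag <- c(rev_flag, is_rev)
    if (is_rev) {
      n_rev <- n_rev + 1L
      if (n_rev > 1L) rev_levels <- c(rev_levels, level)
      had_first_rev <- TRUE
    }
    if (n_rev >= config$reversals_required + 1L) { converged <- TRUE; break }
    step <- if (h && !had_first_rev) config$big_step else config$small_step
    new_level <- q01(max(config$floor_level,
                         min(config$ceiling_level, level + dir * step)))
    pinned <- if (new_level == level) pinned + 1L else 0L
    if (pinned >= 10L) break
    level <- new_level
    dir_prev <- dir
  }
  n <- length(levels)
  trials <- data.frame(index = seq_len(n) - 1L, level = levels,
                       response = heard, is_reversal = rev_flag,
                       phase = rep("none", n))
  est <- if (converged) q01(mean(rev_levels)) else NA_real_
  new_track("bekesy", "quiet", trials, est,
            sprintf("mean of %d good reversals", config$reversals_required),
            converged)
}

#' Configuration for the adaptive gap-detection staircase
#'
#' Single staircase on gap duration: the gap shortens after two consecutive
#' correct identifications; it lengthens (a reversal of direction) after two
#' consecutive misses or after the third cumulative miss since the last
#' reversal. The step halves at each reversal down to `min_step`; the run
#' stops after `stop_reversals` reversals and the threshold estimate is the
#' mean gap at the last `estimator_reversals` reversals.
#'
#' @param start_gap Starting gap, ms.
#' @param initial_step Initial step, ms.
#' @param min_step Floor for the halving step schedule, ms.
#' @param min_gap,max_gap Clamp limits for the gap, ms.
#' @param stop_reversals Reversals required to end the run.
#' @param estimator_reversals Number of final reversals averaged for the
#'   estimate; must not exceed `stop_reversals`.
#' @param miss_reset `"reversal"` (cumulative-miss counter resets at each
#'   reversal; default) or `"never"` (counts misses over the whole run).
#' @param level_axis `"log2"` (listener is queried at log2(gap ms), the
#'   default, see [gap_listener()]) or `"linear"`.
#' @param max_trials Trial cap before the track is flagged non-converged.
#' @return A list of class `gap_config`.
#' @export
gap_config <- function(start_gap = 20, initial_step = 4, min_step = 1,
                       min_gap = 1, max_gap = 100, stop_reversals = 6,
                       estimator_reversals = 4,
                       miss_reset = c("reversal", "never"),
                       level_axis = c("log2", "linear"), max_trials = 400) {
  miss_reset <- match.arg(miss_reset)
  level_axis <- match.arg(level_axis)
  stopifnot(min_gap > 0, start_gap <= max_gap, start_gap >= min_gap,
            initial_step > 0, min_step > 0,
            estimator_reversals <= stop_reversals, stop_reversals >= 2)
  structure(as.list(environment()), class = "gap_config")
}

#' Run the adaptive gap-detection staircase
#'
#' @param listener An [psychometric_listener()] on the axis named by
#'   `config$level_axis`; [gap_listener()] builds the default log2-axis
#'   listener from a threshold in ms.
#' @param config A [gap_config()].
#' @param seed Optional integer seed applied before the run.
#' @return An `aud_track`; `estimate` is the gap threshold in ms, `NA` with
#'   `converged = FALSE` if the track pinned at a gap bound for 10 consecutive
#'   trials or hit the trial cap.
#' @export
run_gap_staircase <- function(listener, config = gap_config(), seed = NULL) {
  stopifnot(inherits(config, "gap_config"))
  if (!is.null(seed)) set.seed(seed)
  gap <- q01(config$start_gap)
  step <- config$initial_step
  consec_correct <- 0L; consec_miss <- 0L; miss_count <- 0L
  dir_prev <- NA_integer_
  n_rev <- 0L
  rev_gaps <- numeric(0)
  pinned <- 0L
  converged <- FALSE
  gaps <- numeric(0); resp <- logical(0); rev_flag <- logical(0)
  for (i in seq_len(config$max_trials)) {
    lvl <- if (config$level_axis == "log2") log2(gap) else gap
    correct <- respond(listener, lvl)
    move <- 0L
    if (correct) {
      consec_correct <- consec_correct + 1L
      consec_miss <- 0L
      if (consec_correct == 2L) { move <- -1L; consec_correct <- 0L }
    } else {
      consec_miss <- consec_miss + 1L
      miss_count <- miss_count + 1L
      consec_correct <- 0L
      if (consec_miss == 2L || miss_count >= 3L) { move <- 1L; consec_miss <- 0L }
    }
    is_rev <- FALSE
    gaps <- c(gaps, gap); resp <- c(resp, correct)
    if (move != 0L) {
      is_rev <- !is.na(dir_prev) && move != dir_prev
      if (is_rev) {
        n_rev <- n_rev + 1L
        rev_gaps <- c(rev_gaps, gap)
        step <- max(step / 2, config$min_step)
        if (config$miss_reset == "reversal") miss_count <- 0L
      }
      dir_prev <- move
      new_gap <- q01(max(config$min_gap, min(config$max_gap, gap + move * step)))
      pinned <- if (new_gap == gap) pinned + 1L else 0L
      gap <- new_gap
    }
    rev_flag <- c(rev_flag, is_rev)
    if (n_rev >= config$stop_reversals) { converged <- TRUE; break }
    if (pinned >= 10L) break
  }
  n <- length(gaps)
  trials <- data.frame(index = seq_len(n) - 1L, level = gaps,
                       response = resp, is_reversal = rev_flag,
                       phase = rep("none", n))
  est <- if (converged)
    mean(utils::tail(rev_gaps, config$estimator_reversals)) else NA_real_
  new_track("gap", "none", trials, est,
            sprintf("mean gap at last %d reversals", config$estimator_reversals),
            converged)
}

#' Configuration for the adaptive Hearing in Noise Test (HINT)
#'
#' A list of `n_sentences` sentences is presented against masking noise fixed
#' at `noise_level_dba` dB(A). The sentence level moves down after a correct
#' whole-sentence repetition and up after an incorrect one, by
#' `step_first_four` dB for sentences 1-4 and `step_rest` dB thereafter
#' (4 then 2 dB in the standard protocol). The speech reception threshold
#' (SRT) is the mean presentation level of all sentences after the first
#' four, expressed as SNR relative to the noise.
#'
#' @param n_sentences Sentences per list (>= 5).
#' @param noise_level_dba Fixed masker level, dB(A); metadata only since the
#'   track works in SNR.
#' @param step_first_four Step for sentences 1-4, dB.
#' @param step_rest Step from sentence 5 on, dB.
#' @param start_snr SNR of the first sentence, dB.
#' @return A list of class `hint_config`.
#' @export
hint_config <- function(n_sentences = 20, noise_level_dba = 65,
                        step_first_four = 4, step_rest = 2, start_snr = 0) {
  stopifnot(n_sentences >= 5, step_first_four > 0, step_rest > 0)
  structure(as.list(environment()), class = "hint_config")
}

#' Run one HINT noise condition
#'
#' @param listener An [psychometric_listener()] on the dB SNR axis; a correct
#'   response means the whole sentence was repeated correctly.
#' @param config A [hint_config()].
#' @param condition One of `"noise_front"`, `"noise_right"`, `"noise_left"`,
#'   `"quiet"`. Conditions differ only through the listener supplied for them.
#' @param seed Optional integer seed applied before the run.
#' @return An `aud_track`; `estimate` is the SRT in dB SNR (mean level of
#'   sentences 5..n).
#' @export
run_hint_condition <- function(listener, config = hint_config(),
                               condition = c("noise_front", "noise_right",
                                             "noise_left", "quiet"),
                               seed = NULL) {
  stopifnot(inherits(config, "hint_config"))
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_sentences
  snr <- numeric(n); correct <- logical(n)
  lvl <- q01(config$start_snr)
  for (i in seq_len(n)) {
    snr[i] <- lvl
    correct[i] <- respond(listener, lvl)
    step <- if (i <= 4L) config$step_first_four else config$step_rest
    lvl <- q01(lvl + if (correct[i]) -step else step)
  }
  moves <- ifelse(correct, -1L, 1L)
  rev_flag <- c(FALSE, moves[-1L] != moves[-n])
  trials <- data.frame(index = seq_len(n) - 1L, level = snr,
                       response = correct, is_reversal = rev_flag,
                       phase = rep("none", n))
  est <- mean(snr[5:n])
  new_track("hint", condition, trials, est,
            sprintf("mean level of sentences 5..%d", n), TRUE)
}

#' Composite HINT SNR across the three noise conditions
#'
#' Unweighted arithmetic mean of the noise-front, noise-right and noise-left
#' SRTs. A missing condition propagates to a missing composite; nothing is
#' imputed. The quiet condition never enters the composite.
#'
#' @param srt_front,srt_right,srt_left Per-condition SRTs in dB SNR.
#' @return Composite SNR in dB (vectorized).
#' @export
hint_composite <- function(srt_front, srt_right, srt_left) {
  (srt_front + srt_right + srt_left) / 3
}

#' Configuration for the digit-triplet test (TDT) with paired maskers
#'
#' Triplets of digits are presented against a masker fixed at
#' `masker_level_db` dB SPL, in pairs of positive- and negative-phase maskers
#' at the same SNR with the within-pair phase order randomized. After each
#' pair the target level moves by `step_per_digit` dB for each incorrect digit
#' minus each correct digit on the pair's positive-phase presentation (so
#' -4.5 to +4.5 dB per pair at the 1.5 dB default). Practice presentations
#' precede the test presentations and never enter the estimate. The SRT is
#' the mean SNR of the last `srt_last_k_positive` positive-phase test
#' presentations.
#'
#' @param n_practice Practice presentations (delivered in pairs; even).
#' @param n_test Test presentations (even); 30 presentations = 15 pairs.
#' @param start_snr Initial SNR, dB.
#' @param masker_level_db Fixed masker level, dB SPL (metadata; track is SNR).
#' @param step_per_digit Level change per digit, dB.
#' @param srt_last_k_positive Positive-phase test presentations averaged for
#'   the SRT; must not exceed `n_test / 2`.
#' @return A list of class `tdt_config`.
#' @export
tdt_config <- function(n_practice = 6, n_test = 30, start_snr = 0,
                       masker_level_db = 75, step_per_digit = 1.5,
                       srt_last_k_positive = 14) {
  stopifnot(n_practice %% 2 == 0, n_test %% 2 == 0, n_test >= 2,
            step_per_digit > 0)
  if (srt_last_k_positive > n_test / 2)
    stop("srt_last_k_positive exceeds the number of positive-phase test presentations")
  structure(as.list(environment()), class = "tdt_config")
}

#' Run the digit-triplet test
#'
#' @param listener An [psychometric_listener()] on the dB SNR axis; its
#'   response to a presentation is the number of digits correct (0..3), with
#'   a closed-set guess rate of 0.1 per digit typical.
#' @param config A [tdt_config()].
#' @param seed Optional integer seed applied before the run (also fixes the
#'   within-pair phase order).
#' @return An `aud_track`; `response` holds digits-correct counts, `phase` the
#'   masker phase, and `estimate` the SRT in dB SNR. Negative-phase responses
#'   are recorded but never drive level updates or the SRT.
#' @export
run_tdt <- function(listener, config = tdt_config(), seed = NULL) {
  stopifnot(inherits(config, "tdt_config"))
  if (!is.null(seed)) set.seed(seed)
  n_pairs_prac <- config$n_practice %/% 2L
  n_pairs_test <- config$n_test %/% 2L
  n_pairs <- n_pairs_prac + n_pairs_test
  lvl <- q01(config$start_snr)
  idx <- 0L
  level <- numeric(0); ndig <- integer(0); phase <- character(0)
  practice <- logical(0)
  pair_lvl <- numeric(n_pairs)
  pos_correct <- integer(n_pairs)
  for (p in seq_len(n_pairs)) {
    order_pos_first <- stats::runif(1L) < 0.5
    phases <- if (order_pos_first) c("positive", "negative") else
      c("negative", "positive")
    pair_lvl[p] <- lvl
    for (ph in phases) {
      k <- respond_triplet(listener, lvl)
      level <- c(level, lvl); ndig <- c(ndig, k); phase <- c(phase, ph)
      practice <- c(practice, p <= n_pairs_prac)
      if (ph == "positive") pos_correct[p] <- k
    }
    delta <- config$step_per_digit * ((3L - pos_correct[p]) - pos_correct[p])
    lvl <- q01(lvl + delta)
  }
  n <- length(level)
  moves <- sign(diff(pair_lvl))
  moves <- moves[moves != 0]
  # reversal bookkeeping on the pair sequence, flagged on positive-phase trials
  pair_rev <- rep(FALSE, n_pairs)
  if (length(moves) > 1) {
    changed <- c(FALSE, moves[-1] != moves[-length(moves)])
    nz <- which(sign(diff(pair_lvl)) != 0)
    pair_rev[nz[changed] + 1L] <- TRUE
  }
  pair_of_trial <- rep(seq_len(n_pairs), each = 2L)
  rev_flag <- pair_rev[pair_of_trial] & phase == "positive"
  trials <- data.frame(index = seq_len(n) - 1L, level = level,
                       response = ndig, is_reversal = rev_flag,
                       phase = phase)
  trials$practice <- practice
  pos_test_lvls <- pair_lvl[(n_pairs_prac + 1L):n_pairs]
  est <- mean(utils::tail(pos_test_lvls, config$srt_last_k_positive))
  new_track("tdt", "none", trials, est,
            sprintf("mean SNR of last %d positive-phase test presentations",
                    config$srt_last_k_positive),
            TRUE)
}
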