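#' Construct a virtual listener with a logistic psychometric function
#'
#' A `psychometric_listener` is the latent per-subject auditory ability that
#' answers simulated trials: the probability of a correct response at stimulus
#' level \eqn{x} is
#' \deqn{p(x) = \gamma + (1 - \gamma - \lambda)\, F(s (x - \theta))}
#' where \eqn{F} is the cumulative logistic, \eqn{\theta} the threshold (the
#' level of 50\%-corrected performance), \eqn{s} the slope, \eqn{\gamma} the
#' guess rate (lower asymptote) and \eqn{\lambda} the lapse rate (1 minus the
#' upper asymptote). Levels follow a "higher is better" convention: dB SNR for
#' speech-in-noise tests, dB HL for tone audibility, and log2(gap in ms) for
#' gap detection (use [gap_listener()] for the latter).
#'
#' In `deterministic_step` mode the listener is a step function: the response
#' is correct if and only if the level is at or above the threshold. This mode
#' is the ground truth for the staircase oracle tests.
#'
#' @param threshold Level of 50%-corrected performance, in the test's stimulus
#'   units.
#' @param slope Steepness of the psychometric function, in 1/units; must be
#'   positive.
#' @param guess_rate Lower asymptote, in `[0, 1)`. Defaults reflect task
#'   structure: 0 for open-set sentence repetition, 1/10 per digit for a
#'   closed set of ten digits.
#' @param lapse_rate One minus the upper asymptote, in `[0, 0.5)`.
#' @param mode `"stochastic"` (Bernoulli responses) or `"deterministic_step"`.
#' @return An object of class `aud_listener`.
#' @examples
#' l <- psychometric_listener(threshold = 2, slope = 1)
#' p_correct(l, 4) # plogis(2)
#' @export
psychometric_listener <- function(threshold, slope = 1, guess_rate = 0,
                                  lapse_rate = 0,
                                  mode = c("stochastic", "deterministic_step")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, is.finite(threshold),
            is.numeric(slope), length(slope) == 1L, is.finite(slope), slope > 0,
            is.numeric(guess_rate), length(guess_rate) == 1L,
            is.numeric(lapse_rate), length(lapse_rate) == 1L)
  if (guess_rate < 0 || guess_rate >= 1)
    stop("guess_rate must lie in [0, 1)")
  if (lapse_rate < 0 || lapse_rate >= 0.5)
    stop("lapse_rate must lie in [0, 0.5)")
  if (guess_rate >= 1 - lapse_rate)
    stop("require guess_rate < 1 - lapse_rate")
  structure(
    list(threshold = threshold, slope = slope, guess_rate = guess_rate,
         lapse_rate = lapse_rate, mode = mode),
    class = "aud_listener"
  )
}

#' Gap-detection listener on the log2(gap) axis
#'
#' Temporal thresholds behave Weber-like, so the gap-detection level axis is
#' log2(gap in ms): doubling the gap is one unit easier. This helper takes a
#' threshold in milliseconds and returns a listener whose threshold is
#' `log2(threshold_ms)`, matching the axis used by [run_gap_staircase()].
#'
#' @param threshold_ms Gap-detection threshold in milliseconds (> 0).
#' @param slope Psychometric slope per log2(ms) unit.
#' @inheritParams psychometric_listener
#' @return An `aud_listener` on the log2(gap ms) axis.
#' @export
gap_listener <- function(threshold_ms, slope = 4, guess_rate = 0,
                         lapse_rate = 0,
                         mode = c("stochastic", "deterministic_step")) {
  stopifnot(is.numeric(threshold_ms), length(threshold_ms) == 1L,
            is.finite(threshold_ms), threshold_ms > 0)
  psychometric_listener(log2(threshold_ms), slope, guess_rate, lapse_rate,
                        match.arg(mode))
}

#' @export
print.aud_listener <- function(x, ...) {
  cat(sprintf("<aud_listener> threshold=%g slope=%g guess=%g lapse=%g mode=%s\n",
              x$threshold, x$slope, x$guess_rate, x$lapse_rate, x$mode))
  invisible(x)
}

#' Probability of a correct response at a stimulus level
#'
#' @param listener An [psychometric_listener()] object.
#' @param level Stimulus level(s), finite, on the listener's axis.
#' @return Probability (vectorized over `level`). In `deterministic_step` mode
#'   returns 0 or 1 (correct iff `level >= threshold`).
#' @export
p_correct <- function(listener, level) {
  stopifnot(inherits(listener, "aud_listener"), is.numeric(level))
  if (any(!is.finite(level))) stop("level must be finite")
  if (listener$mode == "deterministic_step")
    return(as.numeric(level >= listener$threshold))
  listener$guess_rate + (1 - listener$guess_rate - listener$lapse_rate) *
    stats::plogis(listener$slope * (level - listener$threshold))
}

#' Draw a single Bernoulli response from a listener
#'
#' Uses R's global random number stream; seed with [set.seed()] for
#' reproducibility. `deterministic_step` listeners ignore the stream.
#'
#' @inheritParams p_correct
#' @return Logical: was the response correct?
#' @export
respond <- function(listener, level) {
  p <- p_correct(listener, level)
  if (listener$mode == "deterministic_step") return(p >= 1)
  stats::runif(1L) < p
}

#' Number of digits reported correctly in a three-digit triplet
#'
#' Three independent Bernoulli digit trials at the same signal-to-noise ratio,
#' as in digit-triplet speech-in-noise testing.
#'
#' @inheritParams p_correct
#' @param snr Signal-to-noise ratio in dB at which the triplet is presented.
#' @return Integer count in 0..3.
#' @export
respond_triplet <- function(listener, snr) {
  p <- p_correct(listener, snr)
  if (listener$mode == "deterministic_step") return(as.integer(3L * (p >= 1)))
  sum(stats::runif(3L) < p)
}

#' Read listener parameter files
#'
#' Listener parameters are interchanged as JSON: an array of records with keys
#' `test`, `threshold`, `slope`, `guess_rate`, `lapse_rate`, `mode` (and
#' optionally `subject_id`). Requires the jsonlite package.
#'
#' @param path Path to a JSON file.
#' @return A data.frame, one row per listener record.
#' @export
read_listeners <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("reading listener files requires the 'jsonlite' package")
  out <- jsonlite::fromJSON(path)
  need <- c("test", "threshold")
  if (!all(need %in% names(out)))
    stop("listener file must contain at least 'test' and 'threshold' fields")
  if (is.null(out$slope)) out$slope <- 1
  if (is.null(out$guess_rate)) out$guess_rate <- 0
  if (is.null(out$lapse_rate)) out$lapse_rate <- 0
  if (is.null(out$mode)) out$mode <- "stochastic"
  out
}
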