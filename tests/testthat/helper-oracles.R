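# Independently written brute-force traces of each adaptive procedure for
# step-function listeners, deliberately implemented as plain state machines
# that share no code with the package. They return the full level sequence
# and the threshold estimate so tracks can be compared bit-for-bit on the
# 0.1-unit level grid.

grid01 <- function(x) round(x * 10) / 10

# Bekesy-like tracking: heard <=> level >= threshold. Descend in big steps
# until the first direction change, then small steps; ascend in small steps.
# Stop after (n_good + 1) reversals; estimate = mean of reversal levels
# excluding the first, rounded to the grid.
oracle_bekesy <- function(threshold, start = 40, big = 4, small = 2,
                          n_good = 6) {
  level <- grid01(start)
  seen_levels <- c()
  rev_levels <- c()
  last_dir <- 0
  before_first_rev <- TRUE
  repeat {
    heard <- level >= threshold
    seen_levels <- c(seen_levels, level)
    dir <- if (heard) -1 else +1
    if (last_dir != 0 && dir != last_dir) {
      rev_levels <- c(rev_levels, level)
      before_first_rev <- FALSE
    }
    if (length(rev_levels) == n_good + 1) break
    step <- if (heard && before_first_rev) big else small
    level <- grid01(level + dir * step)
    last_dir <- dir
  }
  list(levels = seen_levels,
       estimate = grid01(mean(rev_levels[-1])))
}

# Gap staircase: down after 2 straight correct; up (reversal candidate) after
# 2 straight misses or the 3rd miss since the last reversal; step halves at
# each true direction change down to min_step; stop at stop_rev reversals;
# estimate = mean gap of the last est_rev reversals.
oracle_gap <- function(threshold_ms, start = 20, step0 = 4, min_step = 1,
                       lo = 1, hi = 100, stop_rev = 6, est_rev = 4) {
  gap <- grid01(start)
  step <- step0
  run_correct <- 0; run_miss <- 0; misses <- 0
  last_move <- 0
  revs <- c()
  seen <- c()
  repeat {
    ok <- gap >= threshold_ms
    seen <- c(seen, gap)
    this_move <- 0
    if (ok) {
      run_correct <- run_correct + 1; run_miss <- 0
      if (run_correct == 2) { this_move <- -1; run_correct <- 0 }
    } else {
      run_miss <- run_miss + 1; misses <- misses + 1; run_correct <- 0
      if (run_miss == 2 || misses >= 3) { this_move <- +1; run_miss <- 0 }
    }
    if (this_move != 0) {
      if (last_move != 0 && this_move != last_move) {
        revs <- c(revs, gap)
        step <- max(step / 2, min_step)
        misses <- 0
      }
      last_move <- this_move
      gap <- grid01(min(hi, max(lo, gap + this_move * step)))
    }
    if (length(revs) == stop_rev) break
    if (length(seen) > 10000) stop("oracle runaway")
  }
  list(levels = seen,
       estimate = mean(revs[(length(revs) - est_rev + 1):length(revs)]))
}

# HINT: level moves down after a correct sentence, up after an incorrect
# one; 4 dB for sentences 1-4, 2 dB after; SRT = mean level of sentences
# 5..n.
oracle_hint <- function(threshold, start = 0, n = 20, s14 = 4, s5 = 2) {
  lev <- grid01(start)
  levels <- numeric(n)
  for (i in 1:n) {
    levels[i] <- lev
    ok <- lev >= threshold
    delta <- if (i <= 4) s14 else s5
    lev <- grid01(lev + if (ok) -delta else delta)
  }
  list(levels = levels, estimate = mean(levels[5:n]))
}

# TDT: pairs at a common SNR; digits correct on the positive-phase
# presentation move the level by 1.5 dB per digit (all wrong: +4.5, all
# right: -4.5); 3 practice pairs then 15 test pairs; SRT = mean SNR of the
# last 14 test pairs.
oracle_tdt <- function(threshold, start = 0, per_digit = 1.5,
                       pairs_prac = 3, pairs_test = 15, last_k = 14) {
  lev <- grid01(start)
  pair_levels <- numeric(pairs_prac + pairs_test)
  for (p in seq_along(pair_levels)) {
    pair_levels[p] <- lev
    ndig <- if (lev >= threshold) 3 else 0
    lev <- grid01(lev + per_digit * ((3 - ndig) - ndig))
  }
  test_levels <- pair_levels[(pairs_prac + 1):length(pair_levels)]
  list(pair_levels = pair_levels,
       estimate = mean(test_levels[(pairs_test - last_k + 1):pairs_test]))
}

# Sort-and-cut grouping oracle: type-7 quantiles computed by hand, boundary
# scores assigned to the extreme groups.
oracle_groups <- function(subject_id, hiv_status, score,
                          probs = c(0.2, 0.8)) {
  q7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  qlo <- q7(score, probs[1])
  qhi <- q7(score, probs[2])
  out <- ifelse(hiv_status == "negative", "HIV-negative", "HIV-positive")
  out[hiv_status == "positive" & score <= qlo] <- "BottomCATs"
  out[hiv_status == "positive" & score >= qhi] <- "TopCATs"
  out
}
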