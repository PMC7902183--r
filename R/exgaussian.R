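# Ex-Gaussian response-time model: the convolution of a Normal(mu, sigma^2)
# and an Exponential(mean tau). Response-time distributions rise quickly and
# carry a long positive tail; the fitted mu indexes central processing speed
# while tau absorbs the tail.

check_exg <- function(mu, sigma, tau) {
  stopifnot(is.numeric(mu), is.numeric(sigma), is.numeric(tau),
            length(mu) == 1L, length(sigma) == 1L, length(tau) == 1L,
            is.finite(mu), is.finite(sigma), is.finite(tau))
  if (sigma <= 0) stop("sigma must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  invisible(TRUE)
}

#' Ex-Gaussian density
#'
#' Density of the exponentially modified Gaussian with Gaussian mean `mu`,
#' Gaussian SD `sigma`, and exponential mean `tau` (distribution mean
#' `mu + tau`, variance `sigma^2 + tau^2`). The textbook form
#' \eqn{\tau^{-1} \exp(\sigma^2/2\tau^2 - (x-\mu)/\tau)\,\Phi(z)} with
#' \eqn{z = (x-\mu)/\sigma - \sigma/\tau} loses all precision when
#' \eqn{\sigma/\tau} is large (the exponent and \eqn{\log\Phi(z)} are huge
#' numbers that nearly cancel), so it is evaluated in the equivalent
#' Mills-ratio form
#' \deqn{\log f(x) = \log\phi_{\mu,\sigma}(x) + \log(\sigma/\tau)
#'   + \log\Phi(z) - \log\phi(z)}
#' whose terms are individually well-scaled for any admissible parameters.
#'
#' @param x Quantiles (e.g. response times in ms).
#' @param mu,sigma,tau Parameters; `sigma > 0`, `tau > 0`.
#' @param log Return the log density?
#' @return Density values, vectorized over `x`.
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  check_exg(mu, sigma, tau)
  z <- (x - mu) / sigma - sigma / tau
  logf <- stats::dnorm(x, mu, sigma, log = TRUE) + base::log(sigma / tau) +
    log_mills(z)
  if (log) logf else exp(logf)
}

# log of the Mills ratio Phi(z)/phi(z). The direct log-difference is accurate
# until z^2/2 outgrows double precision; far in the left tail the asymptotic
# expansion -log(-z) + log1p(-1/z^2 + 3/z^4) is exact to machine precision.
log_mills <- function(z) {
  out <- numeric(length(z))
  far <- z < -1e4
  out[!far] <- stats::pnorm(z[!far], log.p = TRUE) -
    stats::dnorm(z[!far], log = TRUE)
  zf <- z[far]
  out[far] <- -base::log(-zf) + log1p(-1 / zf^2 + 3 / zf^4)
  out
}

#' Sample from the ex-Gaussian distribution
#'
#' Each draw is a Normal draw plus an independent Exponential draw; seed the
#' global RNG for reproducibility.
#'
#' @param n Number of samples (>= 1).
#' @inheritParams dexgauss
#' @return Numeric vector of length `n`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  check_exg(mu, sigma, tau)
  stopifnot(n >= 1)
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

exg_moment_start <- function(x, tau_floor) {
  m <- mean(x); s <- stats::sd(x)
  g1 <- mean((x - m)^3) / s^3
  tau0 <- if (g1 > 0) s * (g1 / 2)^(1 / 3) else tau_floor
  tau0 <- min(max(tau0, tau_floor), s)
  sigma0 <- sqrt(max(s^2 - tau0^2, (0.1 * s)^2))
  c(mu = m - tau0, sigma = sigma0, tau = tau0)
}

#' Maximum-likelihood fit of the ex-Gaussian distribution
#'
#' Fits (mu, sigma, tau) by numerical maximum likelihood, optimizing over
#' `(mu, log sigma, log tau)` so positivity needs no constraints. The start is
#' the moment estimator (`tau0` from the sample skewness, clipped to
#' `[tau_floor, s]`). If the optimizer fails, the flagged result carries the
#' moment-based start. Near-symmetric samples pin tau at `tau_floor` with a
#' warning. The returned log-likelihood is never below the start's (the start
#' is kept if the optimizer somehow ends worse).
#'
#' @param x Sample of response times; all finite, `length(x) >= 10`
#'   (n >= 50 recommended).
#' @param tau_floor Smallest admissible tau, in the sample's units
#'   (default 1, i.e. 1 ms for times in ms).
#' @return An object of class `exgauss_fit`: list with `mu`, `sigma`, `tau`,
#'   `loglik`, `converged`, `method` (`"mle"` or `"moments"`), and `n`.
#' @examples
#' set.seed(1)
#' x <- rexgauss(2000, mu = 350, sigma = 40, tau = 120)
#' fit_exgauss(x)
#' @export
fit_exgauss <- function(x, tau_floor = 1) {
  stopifnot(is.numeric(x), length(x) >= 10L)
  if (!all(is.finite(x))) stop("all samples must be finite")
  start <- exg_moment_start(x, tau_floor)
  big <- 1e10 # finite penalty keeps numeric gradients usable
  nll <- function(p) {
    sigma <- exp(p[2]); tau <- exp(p[3])
    if (!all(is.finite(c(p[1], sigma, tau))) || sigma <= 0 || tau <= 0)
      return(big)
    val <- -sum(dexgauss(x, p[1], sigma, tau, log = TRUE))
    if (!is.finite(val)) big else val
  }
  p0 <- c(start["mu"], log(start["sigma"]), log(start["tau"]))
  # Nelder-Mead is robust to the mixed mu / log-scale parameterization;
  # a scaled BFGS pass polishes the optimum.
  opt <- tryCatch(
    stats::optim(p0, nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12)),
    error = function(e) NULL
  )
  if (!is.null(opt)) {
    polish <- tryCatch(
      stats::optim(opt$par, nll, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-12,
                                  parscale = c(max(1, abs(opt$par[1])), 1, 1))),
      error = function(e) NULL
    )
    if (!is.null(polish) && is.finite(polish$value) &&
        polish$value <= opt$value)
      opt <- polish
  }
  nll0 <- nll(p0)
  if (is.null(opt) || !is.finite(opt$value) || opt$value > nll0) {
    out <- list(mu = unname(start["mu"]), sigma = unname(start["sigma"]),
                tau = unname(start["tau"]), loglik = -nll0,
                converged = FALSE, method = "moments", n = length(x))
    return(structure(out, class = "exgauss_fit"))
  }
  tau_hat <- exp(opt$par[3])
  if (tau_hat <= tau_floor * 1.001)
    warning("tau pinned near its floor; sample shows little positive skew")
  out <- list(mu = unname(opt$par[1]), sigma = unname(exp(opt$par[2])),
              tau = unname(tau_hat), loglik = -opt$value,
              converged = opt$convergence == 0, method = "mle",
              n = length(x))
  structure(out, class = "exgauss_fit")
}

#' @export
print.exgauss_fit <- function(x, ...) {
  cat(sprintf(
    "<exgauss_fit> mu=%.2f sigma=%.2f tau=%.2f  logLik=%.2f  n=%d (%s%s)\n",
    x$mu, x$sigma, x$tau, x$loglik, x$n, x$method,
    if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Fit the ex-Gaussian model per subject and visit
#'
#' Convenience wrapper over [fit_exgauss()] for long-format response-time
#' tables: only correct-response times enter the fit, matching the
#' "mean response time of the correct responses" convention. Also returns the
#' plain mean correct response time, the usual companion outcome.
#'
#' @param rt Data frame with columns `subject_id`, `visit`, `rt_ms`,
#'   `correct` (logical or 0/1).
#' @param min_n Minimum number of correct responses to attempt a fit.
#' @return Data frame with one row per subject-visit: `mu`, `sigma`, `tau`,
#'   `mean_rt`, `n_correct`, `converged`.
#' @export
fit_exgauss_by <- function(rt, min_n = 50) {
  need <- c("subject_id", "visit", "rt_ms", "correct")
  if (!all(need %in% names(rt)))
    stop("rt must have columns ", paste(need, collapse = ", "))
  rt <- rt[as.logical(rt$correct), , drop = FALSE]
  keys <- unique(rt[c("subject_id", "visit")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- rt$rt_ms[rt$subject_id == keys$subject_id[i] &
                      rt$visit == keys$visit[i]]
    if (length(sub) < min_n)
      return(data.frame(keys[i, ], mu = NA_real_, sigma = NA_real_,
                        tau = NA_real_, mean_rt = mean(sub),
                        n_correct = length(sub), converged = FALSE))
    f <- fit_exgauss(sub)
    data.frame(keys[i, ], mu = f$mu, sigma = f$sigma, tau = f$tau,
               mean_rt = mean(sub), n_correct = length(sub),
               converged = f$converged)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
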