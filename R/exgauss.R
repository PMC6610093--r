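# Ex-Gaussian reaction-time modelling.
#
# The ex-Gaussian is the convolution of a Normal(mu, sigma) and an
# Exponential(mean tau): mu captures typical response speed, sigma the
# symmetric trial-to-trial spread, and tau the heavy right tail usually
# read as attentional lapses.  Moments: mean = mu + tau,
# var = sigma^2 + tau^2, skewness = 2 tau^3 / (sigma^2 + tau^2)^(3/2).

#' Ex-Gaussian density
#'
#' Closed-form Normal * Exponential convolution density, evaluated in log
#' space (`exp` term plus `pnorm(..., log.p = TRUE)`) so it stays finite for
#' `tau << sigma` and `tau >> sigma`.
#'
#' @param x quantiles (ms).
#' @param mu,sigma,tau parameters in ms; `sigma > 0`, `tau > 0`.
#' @param log return the log-density?
#' @return Density values.
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  if (any(!is.finite(x))) stop("non-finite quantiles")
  stopifnot(sigma > 0, tau > 0)
  z <- (x - mu) / sigma - sigma / tau
  ld <- -base::log(tau) + sigma^2 / (2 * tau^2) - (x - mu) / tau +
    pnorm(z, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' Draw ex-Gaussian reaction times
#'
#' Each draw is `Normal(mu, sigma) + Exponential(mean tau)`.
#'
#' @param n number of draws.
#' @param mu,sigma,tau parameters in ms; `sigma > 0`, `tau > 0`.
#' @return Numeric vector of reaction times (ms).
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stopifnot(n >= 1L, sigma > 0, tau > 0)
  rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)
}

#' Sample a synthetic reaction-time session
#'
#' Thin seeded wrapper over [rexgauss()] taking a parameter triple, used by
#' the cohort generator.
#'
#' @param params named list or vector with `mu`, `sigma`, `tau` (ms).
#' @param n number of trials.
#' @param seed optional integer seed.
#' @return Numeric vector of reaction times (ms).
#' @export
sample_exgaussian_rts <- function(params, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- as.list(params)
  rexgauss(n, p$mu, p$sigma, p$tau)
}

# Moment-based starting values (mean / SD / skewness).
exgauss_moment_init <- function(x) {
  m <- mean(x); s <- sd(x)
  g1 <- mean((x - m)^3) / s^3
  tau0 <- s * (max(g1, 0.01) / 2)^(1 / 3)
  tau0 <- max(tau0, 1e-3)
  list(mu = m - tau0,
       sigma = max(sqrt(max(s^2 - tau0^2, (0.1 * s)^2)), 1e-3),
       tau = tau0)
}

#' Maximum-likelihood ex-Gaussian fit
#'
#' Maximizes the total log-density with box-constrained quasi-Newton
#' optimization (`optim` L-BFGS-B, `sigma, tau >= 1e-3` ms).  Starting
#' values come from the sample moments; two additional deterministic starts
#' with the exponential share halved/doubled guard against local optima in
#' skewed small samples, and the best log-likelihood wins.  Non-convergence
#' of all starts is reported explicitly, never silently.
#'
#' @param rts reaction times in ms; all positive and finite, `n >= 10`
#'   (>= 50 recommended).
#' @param trim optional `c(low, high)` ms window; values outside are
#'   dropped before fitting.  Off by default: the long tail is the object
#'   of interest, not an artifact.
#' @return Object of class `exgauss_fit`: `mu`, `sigma`, `tau`, `loglik`,
#'   `converged`, `n`, `message`.
#' @export
fit_exgauss <- function(rts, trim = NULL) {
  rts <- as.numeric(rts)
  if (any(!is.finite(rts)) || any(rts <= 0))
    stop("reaction times must be positive and finite")
  if (!is.null(trim)) rts <- rts[rts >= trim[1L] & rts <= trim[2L]]
  n <- length(rts)
  if (n < 10L) stop("need at least 10 reaction times, got ", n)
  if (sd(rts) == 0) stop("degenerate sample: zero variance")
  nll <- function(p) {
    if (p[2L] < 1e-3 || p[3L] < 1e-3) return(1e10)   # box for Nelder-Mead too
    v <- -sum(dexgauss(rts, p[1L], p[2L], p[3L], log = TRUE))
    if (!is.finite(v)) 1e10 else v
  }
  init <- exgauss_moment_init(rts)
  starts <- list(
    c(init$mu, init$sigma, init$tau),
    c(init$mu + init$tau / 2, max(init$sigma, 0.5 * sd(rts)),
      max(init$tau / 2, 1e-3)),
    c(init$mu - init$tau / 2, init$sigma, init$tau * 2))
  best <- NULL
  msgs <- character(0L)
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nll, method = "L-BFGS-B",
            lower = c(-Inf, 1e-3, 1e-3),
            control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    msgs <- c(msgs, fit$message %||% "")
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("ex-Gaussian fit failed from every start")
  if (best$convergence != 0L) {
    # L-BFGS-B occasionally aborts its linesearch on noisy numeric
    # gradients; a derivative-free polish from the best point recovers it
    polish <- optim(best$par, nll, method = "Nelder-Mead",
                    control = list(maxit = 2000L, reltol = 1e-10))
    if (polish$value <= best$value) best <- polish
  }
  structure(list(mu = best$par[1L], sigma = best$par[2L], tau = best$par[3L],
                 loglik = -best$value, converged = best$convergence == 0L,
                 n = n,
                 message = if (best$convergence == 0L) "converged"
                           else paste("non-convergence:", best$convergence)),
            class = "exgauss_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.exgauss_fit <- function(x, ...) {
  cat(sprintf("<exgauss_fit> mu = %.2f, sigma = %.2f, tau = %.2f ms (n = %d, logLik = %.2f, %s)\n",
              x$mu, x$sigma, x$tau, x$n, x$loglik, x$message))
  invisible(x)
}

#' Conventional speed/variability summaries of a reaction-time session
#'
#' @param rts reaction times in ms.
#' @param n_stimuli,n_errors optional session totals passed through.
#' @return List with `rt_mean`, `isd` (individual standard deviation,
#'   `n - 1` denominator), `n_trials`, `n_stimuli`, `n_errors`.
#' @export
rt_summary <- function(rts, n_stimuli = NULL, n_errors = NULL) {
  rts <- as.numeric(rts)
  if (!length(rts)) stop("empty reaction-time sample")
  list(rt_mean = mean(rts),
       isd = if (length(rts) >= 2L) sd(rts) else NA_real_,
       n_trials = length(rts),
       n_stimuli = n_stimuli %||% length(rts),
       n_errors = n_errors %||% 0L)
}
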