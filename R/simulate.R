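# Synthetic multichannel EEG with planted phase-lag coupling.
#
# Generative model: the planted tree is rooted at node 1 and edges are
# oriented away from the root.  The root channel is band-limited Gaussian
# noise; each child channel receives its parent's signal rotated by a
# constant phase lag (the band-limited source the edge shares), mixed with a
# private band-limited source according to the edge strength s:
# child = s * rotate(parent, lag) + sqrt(1 - s^2) * private.  Adjacent
# channels therefore show a consistent nonzero lag -- exactly what PLI
# detects -- while siblings share their parent's component at zero relative
# lag, which PLI discounts (much like volume conduction).  At high strengths
# and low noise the spanning tree of strongest PLI connections recovers the
# planted topology.  This generator is a labelled stand-in for real
# recordings, which are not available: it makes the connectivity and tree
# stages verifiable against known ground truth, not a biophysical EEG model.

#' Coupling configuration for the synthetic EEG generator
#'
#' @param band numeric `c(low, high)` frequency interval in Hz.
#' @param rate sampling rate (samples/s), default 500.
#' @param n_samples number of samples to generate (>= 4096).
#' @param lag_per_edge constant phase lag in radians applied along each
#'   edge (default pi/2, the most sign-identifiable lag; even-hop indirect
#'   pairs then sit at lag pi, which PLI discounts).  Must not be a multiple
#'   of pi: a 0 or pi lag has a sign-symmetric phase-difference distribution
#'   and is unidentifiable by PLI.
#' @param noise_sd standard deviation of the independent per-channel
#'   band-limited noise, in signal units (microvolts; default 2).
#' @param amplitude standard deviation of the planted per-channel signal
#'   component (default 10 microvolts).
#' @param seed optional integer seed (`NULL` uses the current RNG stream).
#' @return List of class `coupling_config`.
#' @export
coupling_config <- function(band = c(30, 48), rate = 500, n_samples = 4096L,
                            lag_per_edge = pi / 2, noise_sd = 2,
                            amplitude = 10, seed = NULL) {
  stopifnot(length(band) == 2L)
  if (!(band[1L] > 0 && band[2L] > band[1L] && band[2L] < rate / 2))
    stop("need 0 < band_low < band_high < rate/2")
  n_samples <- as.integer(n_samples)
  if (n_samples < 4096L) stop("n_samples must be at least 4096")
  if (abs(sin(lag_per_edge)) < 1e-9)
    stop("lag_per_edge must not be a multiple of pi (PLI-unidentifiable)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(band = band, rate = rate, n_samples = n_samples,
                 lag_per_edge = lag_per_edge, noise_sd = noise_sd,
                 amplitude = amplitude, seed = seed),
            class = "coupling_config")
}

# Band-limited unit-variance Gaussian noise via spectral masking: white
# noise, FFT, zero all bins outside [low, high], inverse FFT.  Returned as a
# complex analytic-like one-sided reconstruction is avoided; output is real.
band_limited_noise <- function(n, rate, band) {
  x <- rnorm(n)
  f <- (seq_len(n) - 1L) / n * rate
  f <- pmin(f, rate - f)                # two-sided frequency axis
  mask <- f >= band[1L] & f <= band[2L]
  y <- Re(fft(fft(x) * mask, inverse = TRUE) / n)
  y / sd(y)
}

# Shift the phase of a real band-limited signal by a constant angle:
# multiply the positive-frequency half of the spectrum by exp(-1i * lag)
# (and the negative half by the conjugate), i.e. rotate the analytic signal.
phase_shift <- function(x, lag) {
  n <- length(x)
  X <- fft(x)
  rot <- rep(1 + 0i, n)
  if (n %% 2L == 0L) {
    pos <- 2L:(n / 2L)
    neg <- (n / 2L + 2L):n
  } else {
    pos <- 2L:((n + 1L) / 2L)
    neg <- ((n + 3L) / 2L):n
  }
  rot[pos] <- exp(-1i * lag)
  rot[neg] <- exp(1i * lag)
  Re(fft(X * rot, inverse = TRUE) / n)
}

#' Simulate multichannel EEG with a planted coupling tree
#'
#' The tree is rooted at node 1 and traversed away from the root.  The root
#' channel is unit-variance band-limited noise; every child channel is
#' `s * rotate(parent, lag_per_edge) + sqrt(1 - s^2) * private` with `s` the
#' edge strength and `private` an independent band-limited source, so a
#' stronger edge yields a higher expected pairwise PLI (with `s = 1` and no
#' sensor noise the pair's phase difference is the constant lag and PLI is
#' exactly 1).  Channels are scaled to `amplitude` standard deviation and
#' independent band-limited sensor noise of SD `noise_sd` is added, keeping
#' the output on a realistic microvolt scale.  Deterministic given
#' `cfg$seed`.
#'
#' @param tree a [tree_spec()].
#' @param cfg a [coupling_config()].
#' @param labels channel labels; defaults to the first `n_nodes` entries of
#'   [analysis_labels()] when they fit, else `N1..Nk`.
#' @return An [eeg_recording()].
#' @export
simulate_coupled_eeg <- function(tree, cfg, labels = NULL) {
  stopifnot(inherits(tree, "tree_spec"), inherits(cfg, "coupling_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_ch <- tree$n_nodes
  if (is.null(labels)) {
    labels <- if (n_ch <= 19L) analysis_labels()[seq_len(n_ch)]
              else paste0("N", seq_len(n_ch))
  }
  n <- cfg$n_samples
  # orient edges away from the root (node 1) by BFS
  adj <- vector("list", n_ch)
  strength <- vector("list", n_ch)
  for (e in seq_len(nrow(tree$edges))) {
    i <- tree$edges[e, 1L]; j <- tree$edges[e, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    strength[[i]] <- c(strength[[i]], tree$edge_strengths[e])
    strength[[j]] <- c(strength[[j]], tree$edge_strengths[e])
  }
  sig <- matrix(0, n_ch, n)
  sig[1L, ] <- band_limited_noise(n, cfg$rate, cfg$band)
  visited <- c(TRUE, rep(FALSE, n_ch - 1L))
  queue <- 1L
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (k in seq_along(adj[[u]])) {
      v <- adj[[u]][k]
      if (visited[v]) next
      visited[v] <- TRUE
      s <- strength[[u]][k]
      child <- s * phase_shift(sig[u, ], cfg$lag_per_edge)
      if (s < 1)
        child <- child + sqrt(1 - s^2) * band_limited_noise(n, cfg$rate, cfg$band)
      sig[v, ] <- child
      queue <- c(queue, v)
    }
  }
  for (ch in seq_len(n_ch)) {
    s <- sd(sig[ch, ])
    if (s > 0) sig[ch, ] <- sig[ch, ] / s * cfg$amplitude
    if (cfg$noise_sd > 0)
      sig[ch, ] <- sig[ch, ] + cfg$noise_sd *
        band_limited_noise(n, cfg$rate, cfg$band)
  }
  eeg_recording(sig, cfg$rate, labels)
}
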