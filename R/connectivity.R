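# Phase lag index (PLI) functional connectivity.
#
# PLI measures the asymmetry of the distribution of instantaneous phase
# differences between two signals: |< sign(delta_phi(t)) >|.  It is 0 for
# symmetric (or strictly zero-lag) phase differences and 1 for a lag of
# fixed sign, which makes it insensitive to common-source / volume-conduction
# coupling.  Phases come from the analytic signal (FFT Hilbert transform).

# One-sided spectrum analytic signal.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  if (any(!is.finite(x))) stop("non-finite values in series")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a signal
#'
#' Phase of the analytic signal (Hilbert transform) at each sample, wrapped
#' to (-pi, pi].
#'
#' @param x finite numeric series, length >= 2.
#' @return Numeric vector of phases in radians.
#' @export
instantaneous_phase <- function(x) {
  if (all(x == 0)) stop("phase of the all-zero series is undefined")
  Arg(analytic_signal(x))
}

# Wrap angles to (-pi, pi].
wrap_phase <- function(d) atan2(sin(d), cos(d))

#' PLI from a series of phase differences
#'
#' `|mean(sign(wrapped delta phi))|`.  `sign(0)` contributes 0, so exactly
#' zero-lag samples are discounted (identical signals give PLI 0).
#'
#' @param dphi phase differences in radians (wrapped internally).
#' @return Scalar in \[0, 1\].
#' @export
pli_from_delta <- function(dphi) {
  if (!length(dphi)) stop("empty phase-difference series")
  abs(mean(sign(wrap_phase(dphi))))
}

#' Phase lag index of a signal pair
#'
#' @param x,y equal-length numeric series.
#' @return Scalar in \[0, 1\]; 0 for symmetric or zero-lag phase
#'   differences, 1 for a constant-sign lag.
#' @export
pli_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  pli_from_delta(instantaneous_phase(x) - instantaneous_phase(y))
}

#' Connectivity matrix container
#'
#' Symmetric channels-by-channels matrix of values in \[0, 1\] with a zero
#' diagonal.
#'
#' @param values symmetric numeric matrix.
#' @param labels channel labels.
#' @param band optional band tag.
#' @export
conn_matrix <- function(values, labels = rownames(values), band = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(labels)) labels <- paste0("N", seq_len(n))
  if (length(labels) != n || ncol(values) != n)
    stop("values must be square with one label per channel")
  if (max(abs(values - t(values))) > 1e-10) stop("matrix must be symmetric")
  if (any(diag(values) != 0)) stop("diagonal must be zero")
  if (any(values < -1e-12) || any(values > 1 + 1e-12))
    stop("entries must lie in [0, 1]")
  values <- pmin(pmax((values + t(values)) / 2, 0), 1)
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = as.character(labels), band = band),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat("<conn_matrix>", nrow(x$values), "channels",
      if (!is.null(x$band)) paste0("[", x$band, "]"),
      "| mean PLI", round(global_pli(x), 4), "\n")
  invisible(x)
}

#' PLI matrix over all channel pairs of one epoch
#'
#' @param epoch channels-by-samples numeric matrix, or an
#'   [eeg_recording()].
#' @param labels channel labels (taken from the recording if given).
#' @param band optional band tag.
#' @return A [conn_matrix()].
#' @export
pli_matrix <- function(epoch, labels = NULL, band = NULL) {
  if (inherits(epoch, "eeg_recording")) {
    labels <- epoch$labels
    epoch <- epoch$samples
  }
  epoch <- as.matrix(epoch)
  n <- nrow(epoch)
  if (n < 2L) stop("need at least 2 channels")
  if (is.null(labels)) labels <- rownames(epoch)
  # sign(wrapped phase difference) == sign(Im(z_i * conj(z_j))) for analytic
  # signals z, since Im(z_i conj(z_j)) = |z_i||z_j| sin(phi_i - phi_j):
  # evaluating the cross term avoids per-pair trigonometry and is exactly
  # equivalent to pli_pair() (property-tested).
  z <- matrix(0i, n, ncol(epoch))
  for (ch in seq_len(n)) {
    if (all(epoch[ch, ] == 0))
      stop("channel ", labels[ch], ": phase of all-zero series is undefined")
    z[ch, ] <- analytic_signal(epoch[ch, ])
  }
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    zi <- z[i, ]
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- abs(mean(sign(Im(zi * Conj(z[j, ])))))
    }
  }
  conn_matrix(m, labels, band = band)
}

#' Element-wise average of connectivity matrices
#'
#' Per-subject connectivity is the mean of the per-epoch PLI matrices.
#'
#' @param mats non-empty list of [conn_matrix()] with identical labels.
#' @return A [conn_matrix()].
#' @export
average_matrices <- function(mats) {
  if (!length(mats)) stop("empty list of matrices")
  labs <- mats[[1L]]$labels
  for (m in mats) {
    stopifnot(inherits(m, "conn_matrix"))
    if (!identical(m$labels, labs)) stop("label mismatch across matrices")
  }
  conn_matrix(Reduce(`+`, lapply(mats, `[[`, "values")) / length(mats),
              labs, band = mats[[1L]]$band)
}

#' Global PLI: mean over all unordered channel pairs
#'
#' @param mat a [conn_matrix()].
#' @return Scalar mean of the strict upper triangle.
#' @export
global_pli <- function(mat) {
  stopifnot(inherits(mat, "conn_matrix"))
  v <- mat$values
  if (nrow(v) < 2L) stop("need at least 2 channels")
  mean(v[upper.tri(v)])
}
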