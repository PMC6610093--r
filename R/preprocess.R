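# Preprocessing: common average reference, zero-phase FIR band filtering,
# epoching and automated artifact-based epoch selection.

#' Default analysis frequency bands (Hz)
#'
#' delta 0.5-4, theta 4-8, lower alpha 8-10, upper alpha 10-12, beta 13-30,
#' gamma 30-48.  The alpha range is split because its sub-bands engage
#' different cognitive processes; low gamma is retained for its prominence
#' in psychosis research.
#'
#' @return Named list of `c(low, high)` intervals.
#' @export
band_set <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), lower_alpha = c(8, 10),
       upper_alpha = c(10, 12), beta = c(13, 30), gamma = c(30, 48))
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over a reference electrode set from
#' every channel.  Frontopolar (Fp1/Fp2) and ear (A1/A2) electrodes are
#' excluded from the reference by default because of EMG contamination, and
#' A1/A2 are dropped from the output entirely; Fp1/Fp2 stay in the output.
#'
#' @param rec an [eeg_recording()].
#' @param exclude labels excluded from the reference computation.
#' @param drop labels removed from the output recording.
#' @return The re-referenced [eeg_recording()].
#' @export
rereference_common_average <- function(rec,
                                       exclude = c("Fp1", "Fp2", "A1", "A2"),
                                       drop = c("A1", "A2")) {
  stopifnot(inherits(rec, "eeg_recording"))
  bad <- setdiff(exclude, rec$labels)
  # tolerate exclusions naming channels absent from this recording
  ref_labels <- setdiff(rec$labels, exclude)
  if (length(ref_labels) < 2L)
    stop("common average reference needs at least 2 reference channels, got ",
         length(ref_labels))
  ref <- colMeans(rec$samples[ref_labels, , drop = FALSE])
  out <- sweep(rec$samples, 2L, ref)
  keep <- setdiff(rec$labels, drop)
  eeg_recording(out[keep, , drop = FALSE], rec$rate, keep)
}

# --- FIR design and zero-phase application ---------------------------------

# Hamming-windowed sinc band-pass.  Half-amplitude cutoffs are placed half a
# transition width *outside* the stated band edges, so the passband proper is
# [low, high] with ~unit gain and the response has decayed to the stopband by
# one transition width beyond each edge (Hamming stopband ~ -53 dB, well past
# the 20 dB requirement).  Filter length ~ 3.3 / normalized transition width.
fir_bandpass_design <- function(low, high, rate,
                                trans_low = NULL, trans_high = NULL) {
  if (!(low > 0 && high > low && high < rate / 2))
    stop("band edges must satisfy 0 < low < high < rate/2")
  if (is.null(trans_low)) trans_low <- min(1, low)
  if (is.null(trans_high)) trans_high <- min(1, (rate / 2 - high))
  lc <- (low - trans_low / 2) / rate
  hc <- (high + trans_high / 2) / rate
  ntaps <- ceiling(3.3 * rate / min(trans_low, trans_high))
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  m <- seq_len(ntaps) - 1L - (ntaps - 1L) / 2
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  h <- 2 * hc * sinc(2 * hc * m) - 2 * lc * sinc(2 * lc * m)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(ntaps) - 1L) / (ntaps - 1L))
  h <- h * w
  fc <- (low + high) / 2 / rate                 # normalize centre-band gain
  g <- Mod(sum(h * exp(-2i * pi * fc * m)))
  h / g
}

# Linear-phase FIR applied with group-delay compensation: for a symmetric
# kernel this is exactly zero-phase.  Edges are zero-padded; callers that
# care simulate with margin and trim.  Convolution runs over an FFT padded
# to a 2-3-5-smooth length (stats::convolve pads to n + m - 1, which can hit
# a large prime factor and degrade the FFT to near-quadratic cost).
apply_fir <- function(x, h) {
  d <- (length(h) - 1L) / 2L
  n <- length(x)
  N <- stats::nextn(n + length(h) - 1L)
  H <- fft(c(h, numeric(N - length(h))))
  y <- Re(fft(fft(c(x, numeric(N - n))) * H, inverse = TRUE)) / N
  y[(d + 1L):(d + n)]
}

# Same, for a channels x samples matrix, computing the kernel FFT once.
apply_fir_matrix <- function(m, h) {
  d <- (length(h) - 1L) / 2L
  n <- ncol(m)
  N <- stats::nextn(n + length(h) - 1L)
  H <- fft(c(h, numeric(N - length(h))))
  out <- m
  for (ch in seq_len(nrow(m))) {
    y <- Re(fft(fft(c(m[ch, ], numeric(N - n))) * H, inverse = TRUE)) / N
    out[ch, ] <- y[(d + 1L):(d + n)]
  }
  out
}

#' Zero-phase band-pass filter
#'
#' Hamming-window FIR filtering of every channel, with the symmetric-kernel
#' delay compensated so the output is zero-phase.  Out-of-band components
#' are attenuated by at least 20 dB one transition width beyond the band
#' edges.
#'
#' @param rec an [eeg_recording()].
#' @param band numeric `c(low, high)` in Hz, inside (0, rate/2).
#' @param trans_low,trans_high transition widths in Hz; defaults
#'   `min(1, low)` and `min(1, rate/2 - high)`.
#' @return The filtered [eeg_recording()].
#' @export
bandpass <- function(rec, band, trans_low = NULL, trans_high = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), length(band) == 2L)
  h <- fir_bandpass_design(band[1L], band[2L], rec$rate, trans_low, trans_high)
  eeg_recording(apply_fir_matrix(rec$samples, h), rec$rate, rec$labels)
}

# --- epoching ---------------------------------------------------------------

#' Epoch set container
#'
#' @param data numeric array `channels x samples x epochs`.
#' @param rate sampling rate.
#' @param labels channel labels.
#' @param band optional band tag.
#' @export
epoch_set <- function(data, rate, labels, band = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            dim(data)[1L] == length(labels))
  structure(list(data = data, rate = rate, labels = as.character(labels),
                 band = band), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set>", d[3L], "epochs x", d[1L], "channels x", d[2L],
      "samples", if (!is.null(x$band)) paste0("[", x$band, "]"), "\n")
  invisible(x)
}

#' @rdname epoch_set
#' @export
n_epochs <- function(x) dim(x$data)[3L]

#' Segment a recording into fixed-length epochs
#'
#' Non-overlapping consecutive segments; any trailing remainder shorter than
#' one epoch is discarded.  The default of 4096 samples is ~8 s at 500 Hz.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_len epoch length in samples.
#' @param band optional band tag carried on the result.
#' @return An [epoch_set()].
#' @export
epoch_recording <- function(rec, epoch_len = 4096L, band = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  epoch_len <- as.integer(epoch_len)
  n <- ncol(rec$samples)
  if (n < epoch_len)
    stop("recording (", n, " samples) shorter than one epoch (", epoch_len, ")")
  k <- n %/% epoch_len
  arr <- array(rec$samples[, seq_len(k * epoch_len)],
               dim = c(nrow(rec$samples), epoch_len, k))
  epoch_set(arr, rec$rate, rec$labels, band = band)
}

#' Automated artifact-based epoch selection
#'
#' Stand-in for expert visual artifact rejection: an epoch is inadmissible
#' if any channel exceeds `amp_limit` in absolute amplitude (railed or
#' movement-contaminated channels) or if its mean channel variance is an
#' outlier (z-score above `var_z_limit`) relative to the other epochs.  The
#' `k` admissible epochs with the lowest peak amplitude are returned, ties
#' keeping their original order.
#'
#' @param epochs an [epoch_set()].
#' @param k number of epochs to keep (default 30).
#' @param amp_limit absolute amplitude limit in signal units (default 100,
#'   i.e. the conventional +/-100 microvolt rejection threshold).
#' @param var_z_limit variance z-score limit (default 4).
#' @return An [epoch_set()] with exactly `k` epochs; attribute `"selected"`
#'   holds the original epoch indices.  Fewer than `k` admissible epochs is
#'   an error, never silent padding.
#' @export
select_epochs <- function(epochs, k = 30L, amp_limit = 100, var_z_limit = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  ne <- n_epochs(epochs)
  peak <- apply(abs(epochs$data), 3L, max)
  vmean <- apply(epochs$data, 3L, function(ep) mean(apply(ep, 1L, var)))
  vz <- if (length(vmean) > 1L && sd(vmean) > 0)
    abs(vmean - mean(vmean)) / sd(vmean) else rep(0, ne)
  admissible <- which(peak < amp_limit & vz <= var_z_limit)
  if (length(admissible) < k)
    stop("only ", length(admissible), " admissible epochs; ", k, " requested")
  ord <- admissible[order(peak[admissible])]    # order() is stable
  sel <- ord[seq_len(k)]                        # lowest artifact score first
  out <- epoch_set(epochs$data[, , sel, drop = FALSE], epochs$rate,
                   epochs$labels, band = epochs$band)
  attr(out, "selected") <- sel
  out
}
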