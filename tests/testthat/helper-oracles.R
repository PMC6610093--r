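# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by different routes than the package
# (enumeration, direct formulas, quadrature) so they can catch shared bugs.

# Decode a Pruefer sequence (independent implementation for the exhaustive
# spanning-tree oracle: iterates over a working degree vector).
oracle_prufer_decode <- function(seq, n) {
  deg <- rep(1L, n)
  for (s in seq) deg[s] <- deg[s] + 1L
  out <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(seq)) {
    l <- which.min(ifelse(deg == 1L, seq_len(n), Inf))
    out[i, ] <- c(l, seq[i])
    deg[l] <- deg[l] - 1L
    deg[seq[i]] <- deg[seq[i]] - 1L
  }
  out[n - 1L, ] <- which(deg == 1L)
  out
}

# Maximum total weight over every labelled spanning tree of K_n (Cayley:
# n^(n-2) trees), by brute-force enumeration of all Pruefer sequences.
oracle_max_tree_weight <- function(w) {
  n <- nrow(w)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- oracle_prufer_decode(seqs[r, ], n)
    best <- max(best, sum(w[ed]))
  }
  best
}

# Sorted canonical edge keys of a spanning_tree, for planted-vs-recovered
# comparisons.
edge_key <- function(tree) {
  sort(paste(pmin(tree$edges$from, tree$edges$to),
             pmax(tree$edges$from, tree$edges$to)))
}

# Cumulative unwrapped phase from a wrapped phase series.
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- atan2(sin(d), cos(d))
  cumsum(c(phi[1L], d))
}

# Random symmetric PLI-like matrix in (0, 1) with zero diagonal.
random_pli_matrix <- function(n, labels = paste0("N", seq_len(n))) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1L) / 2, 0.05, 0.95)
  m <- m + t(m)
  dimnames(m) <- list(labels, labels)
  m
}

# Small multichannel sine recording.
sine_recording <- function(freqs, rate = 500, secs = 8,
                           labels = paste0("N", seq_along(freqs))) {
  t <- seq(0, secs - 1 / rate, by = 1 / rate)
  eeg_recording(t(vapply(freqs, function(f) sin(2 * pi * f * t),
                         numeric(length(t)))), rate, labels)
}
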