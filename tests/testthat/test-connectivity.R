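test_that("instantaneous phase matches the analytic-signal identities", {
  rate <- 500
  t <- seq(0, 8 - 1 / rate, by = 1 / rate)     # integer number of cycles
  ph_cos <- instantaneous_phase(cos(2 * pi * 10 * t))
  inc <- diff(unwrap_phase(ph_cos))
  expect_equal(mean(inc), 2 * pi * 10 / rate, tolerance = 1e-8)

  # sin is cos delayed by pi/2
  ph_sin <- instantaneous_phase(sin(2 * pi * 10 * t))
  d <- atan2(sin(ph_sin - ph_cos), cos(ph_sin - ph_cos))
  expect_equal(median(d[100:3900]), -pi / 2, tolerance = 1e-6)

  # band-limited noise: mean phase increment sits at the periodogram peak
  set.seed(10)
  x <- mstnet:::band_limited_noise(4096, rate, c(8, 12))
  inc <- diff(unwrap_phase(instantaneous_phase(x)))
  f_phase <- mean(inc) * rate / (2 * pi)
  spec <- Mod(fft(x))^2
  f_axis <- (seq_along(x) - 1) / length(x) * rate
  f_peak <- sum(f_axis[f_axis < 250] * spec[f_axis < 250]) /
    sum(spec[f_axis < 250])
  expect_equal(f_phase, f_peak, tolerance = 0.05)

  expect_error(instantaneous_phase(numeric(4096)), "all-zero")
})

test_that("PLI analytics: zero lag, constant lag, sign mixtures", {
  set.seed(11)
  x <- mstnet:::band_limited_noise(4096, 500, c(8, 12))
  expect_identical(pli_pair(x, x), 0)          # sign(0) convention

  # constant pi/4 lag: every phase-difference sign identical
  tr <- tree_spec(2, cbind(1, 2), edge_strengths = 1)
  cfg <- coupling_config(band = c(8, 12), n_samples = 4096,
                         lag_per_edge = pi / 4, noise_sd = 0, seed = 12)
  rec <- simulate_coupled_eeg(tr, cfg)
  expect_identical(pli_pair(rec$samples[1L, ], rec$samples[2L, ]), 1)

  # 75% / 25% sign mixture -> |0.75 - 0.25| by direct sign counting
  expect_identical(pli_from_delta(c(rep(pi / 4, 75), rep(-pi / 4, 25))), 0.5)
  # same construction at signal level: two lagged blocks
  y <- c(mstnet:::phase_shift(x, pi / 4)[1:3072],
         mstnet:::phase_shift(x, -pi / 4)[3073:4096])
  expect_equal(pli_pair(x, y), 0.5, tolerance = 0.05)

  # amplitude-scaling invariance and symmetry
  z <- mstnet:::band_limited_noise(4096, 500, c(8, 12))
  expect_identical(pli_pair(5 * x, 0.1 * z), pli_pair(x, z))
  expect_identical(pli_pair(x, z), pli_pair(z, x))
  expect_error(pli_pair(x, z[1:100]), "length mismatch")
})

test_that("pli_matrix fills every pair and matches pli_pair", {
  set.seed(13)
  ep <- matrix(rnorm(19 * 2048), 19)
  m <- pli_matrix(ep, labels = analysis_labels())
  v <- m$values
  expect_identical(sum(upper.tri(v)), 171L)          # C(19, 2) pairs
  expect_true(all(v[upper.tri(v)] >= 0 & v[upper.tri(v)] <= 1))
  expect_identical(v, t(v))
  expect_identical(unname(diag(v)), rep(0, 19))
  for (i in c(1L, 7L)) for (j in c(12L, 19L))
    expect_equal(v[i, j], pli_pair(ep[i, ], ep[j, ]))
  expect_error(pli_matrix(ep[1, , drop = FALSE]), "at least 2 channels")
})

test_that("independent noise gives near-zero PLI, shrinking with length", {
  set.seed(14)
  null_mean <- function(len) {
    m <- pli_matrix(matrix(rnorm(8 * len), 8))
    mean(m$values[upper.tri(m$values)])
  }
  m1 <- null_mean(4096)
  expect_lt(m1, 0.1)
  expect_lt(null_mean(8192), m1)
  expect_lt(null_mean(16384), m1)
})

test_that("star-coupled epochs put the highest mean PLI on the hub", {
  tr <- make_reference_tree("star", 10, edge_strengths = 0.95)
  cfg <- coupling_config(band = c(8, 12), n_samples = 4096, noise_sd = 1,
                         seed = 15)
  rec <- simulate_coupled_eeg(tr, cfg)
  m <- pli_matrix(rec)
  expect_identical(unname(which.max(rowMeans(m$values))), 1L)
})

test_that("matrix averaging preserves invariants and handles errors", {
  set.seed(16)
  a <- pli_matrix(matrix(rnorm(4 * 1024), 4), labels = c("F3", "F4", "P3", "P4"))
  b <- pli_matrix(matrix(rnorm(4 * 1024), 4), labels = c("F3", "F4", "P3", "P4"))
  expect_equal(average_matrices(rep(list(a), 30))$values, a$values)
  expect_equal(average_matrices(list(a, b))$values, (a$values + b$values) / 2)
  expect_error(average_matrices(list()), "empty")
  c2 <- pli_matrix(matrix(rnorm(4 * 1024), 4), labels = c("F3", "F4", "P3", "Pz"))
  expect_error(average_matrices(list(a, c2)), "label mismatch")
})

test_that("global PLI is the mean of the strict upper triangle", {
  m3 <- matrix(0, 3, 3)
  m3[upper.tri(m3)] <- c(0.1, 0.2, 0.3)
  m3 <- m3 + t(m3)
  expect_equal(global_pli(conn_matrix(m3)), 0.2)
  all4 <- matrix(0.4, 4, 4); diag(all4) <- 0
  expect_equal(global_pli(conn_matrix(all4)), 0.4)
  expect_equal(global_pli(conn_matrix(matrix(0, 5, 5))), 0)
})
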