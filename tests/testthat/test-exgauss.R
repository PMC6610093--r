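test_that("ex-Gaussian density is normalized and matches quadrature", {
  expect_equal(stats::integrate(dexgauss, -2000, 20000, mu = 500, sigma = 50,
                                tau = 200)$value, 1, tolerance = 1e-6)
  # brute-force Normal * Exponential convolution at several points; the
  # integrand is a narrow bump near s = x0 - mu, so integrate over a finite
  # window that certainly contains it
  for (x0 in c(400, 600, 900, 1500)) {
    conv <- stats::integrate(function(s) dnorm(x0 - s, 500, 50) *
                               stats::dexp(s, 1 / 200),
                             max(0, x0 - 500 - 800), x0 - 500 + 800,
                             rel.tol = 1e-12, abs.tol = 1e-16)$value
    expect_equal(dexgauss(x0, 500, 50, 200), conv, tolerance = 1e-8)
  }
  # tau -> 0+ pointwise Gaussian limit, stable for tau << sigma
  xs <- seq(300, 700, by = 50)
  expect_equal(dexgauss(xs, 500, 50, 1e-3), dnorm(xs, 500, 50),
               tolerance = 1e-4)
  # tau >> sigma stays finite in log space
  expect_true(all(is.finite(dexgauss(xs, 500, 1e-2, 5000, log = TRUE))))
  expect_error(dexgauss(Inf, 500, 50, 200), "non-finite")
})

test_that("MLE recovers generating parameters on large samples", {
  set.seed(29)
  x <- rexgauss(2e4, 990.44, 78.31, 673.93)
  f <- fit_exgauss(x)
  expect_true(f$converged)
  expect_equal(f$mu, 990.44, tolerance = 0.02)
  expect_equal(f$tau, 673.93, tolerance = 0.03)
  y <- rexgauss(2e4, 765.19, 90.81, 455.23)
  g <- fit_exgauss(y)
  expect_equal(g$tau, 455.23, tolerance = 0.03)
})

test_that("symmetric Gaussian samples drive tau to its boundary", {
  # an exactly symmetric sample has zero skewness, so the exponential
  # component collapses and the fit reduces to the direct Gaussian MLE
  set.seed(30)
  half <- rnorm(2500, 800, 50)
  z <- c(half, 2 * mean(half) - half)
  f <- fit_exgauss(z)
  expect_lt(f$tau, 2)                        # at/near the 1e-3 lower bound
  expect_equal(f$mu + f$tau, mean(z), tolerance = 5e-3)
  expect_equal(f$sigma, sd(z) * sqrt((length(z) - 1) / length(z)),
               tolerance = 0.02)
  gauss_ll <- sum(dnorm(z, mean(z), sd(z) * sqrt((length(z) - 1) / length(z)),
                        log = TRUE))
  expect_gte(f$loglik, gauss_ll - 1e-3)      # no worse than the Gaussian MLE
})

test_that("estimates are shift- and scale-equivariant", {
  set.seed(31)
  x <- rexgauss(2000, 600, 60, 250)
  f0 <- fit_exgauss(x)
  fs <- fit_exgauss(x + 300)
  expect_equal(fs$mu, f0$mu + 300, tolerance = 1e-2)
  expect_equal(fs$sigma, f0$sigma, tolerance = 1e-2)
  expect_equal(fs$tau, f0$tau, tolerance = 1e-2)
  fk <- fit_exgauss(x * 2)
  expect_equal(fk$mu, f0$mu * 2, tolerance = 0.01)
  expect_equal(fk$sigma, f0$sigma * 2, tolerance = 0.05)
  expect_equal(fk$tau, f0$tau * 2, tolerance = 0.01)
})

test_that("session-sized samples recover mu within 10% in the median", {
  set.seed(32)
  rel_err <- replicate(100, {
    x <- rexgauss(60, 990.44, 78.31, 673.93)
    abs(fit_exgauss(x)$mu - 990.44) / 990.44
  })
  expect_lte(median(rel_err), 0.10)
})

test_that("degenerate reaction-time samples are rejected loudly", {
  expect_error(fit_exgauss(c(500, 600)), "at least 10")
  expect_error(fit_exgauss(rep(500, 50)), "zero variance")
  expect_error(fit_exgauss(c(rnorm(50, 500, 10), -5)), "positive")
  expect_error(fit_exgauss(c(rnorm(50, 500, 10), NA)), "positive")
})

test_that("summary statistics follow the hand calculations", {
  s <- rt_summary(c(1000, 1200))
  expect_equal(s$rt_mean, 1100)
  expect_equal(s$isd, sqrt((100^2 + 100^2) / 1))   # n - 1 denominator
  expect_equal(round(s$isd, 2), 141.42)
  expect_equal(rt_summary(rep(700, 10))$isd, 0)
  set.seed(33)
  big <- rt_summary(rexgauss(1e5, 500, 50, 200))
  expect_equal(big$rt_mean, 700, tolerance = 0.01)
  expect_error(rt_summary(numeric(0)), "empty")
  s2 <- rt_summary(c(900, 950), n_stimuli = 60, n_errors = 3)
  expect_identical(s2$n_stimuli, 60)
  expect_identical(s2$n_errors, 3)
})
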