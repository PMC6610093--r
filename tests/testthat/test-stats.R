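test_that("log transform applies the 1e-24 zero correction", {
  expect_equal(log_transform(1), 0, tolerance = 1e-15)
  expect_equal(log_transform(0), log(1e-24))
  expect_equal(log_transform(0), -55.262, tolerance = 1e-3)
  expect_equal(log_transform(exp(1) - 1e-24), 1)
  expect_error(log_transform(-0.1), "non-negative")
  x <- c(0, 0.2, 0.5, 0.9)
  expect_true(all(diff(log_transform(x)) > 0))   # monotone
})

test_that("ANCOVA group effect matches explicit sums-of-squares algebra", {
  # 6-row hand dataset, worked through raw matrix algebra below
  d <- data.frame(group = factor(c("HC", "HC", "HC", "SZ", "SZ", "SZ")),
                  age = c(21, 22, 23, 21, 22, 24),
                  y = c(10, 12, 11, 15, 17, 20))
  eff <- ancova_group_effect(d, "y", covariates = "age")
  X_full <- cbind(1, as.numeric(d$group == "SZ"), d$age)
  X_red <- cbind(1, d$age)
  rss <- function(X, y) {
    b <- solve(crossprod(X), crossprod(X, d$y))
    sum((d$y - X %*% b)^2)
  }
  ss_group <- rss(X_red) - rss(X_full)
  F_hand <- ss_group / (rss(X_full) / 3)       # df2 = 6 - 2 - 1
  expect_equal(eff$F, F_hand, tolerance = 1e-10)
  expect_equal(eff$eta_p_sq, ss_group / (ss_group + rss(X_full)),
               tolerance = 1e-10)
  expect_identical(eff$df, c(1L, 3L))
  expect_identical(eff$direction, 1)           # SZ adjusted mean higher

  # identical outcomes in both groups: no group effect at all
  d2 <- data.frame(group = factor(rep(c("HC", "SZ"), each = 10)),
                   age = rep(21:30, 2), y = rep(sin(1:10) * 3 + 20, 2))
  eff2 <- ancova_group_effect(d2, "y", covariates = "age")
  expect_lt(abs(eff2$F), 1e-8)
  expect_lt(abs(eff2$eta_p_sq), 1e-8)

  # n = 70 with three covariates: denominator df 65
  pre <- cohort_preset_default(35)
  co <- generate_cohort(pre, seed = 45)
  eff3 <- ancova_group_effect(co, "mu")
  expect_identical(eff3$df, c(1L, 65L))

  co$age2 <- co$age * 2                        # collinear covariate
  expect_error(ancova_group_effect(co, "mu",
                                   covariates = c("age", "age2")),
               "collinear")
})

test_that("Bonferroni correction multiplies, caps and preserves order", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 10), 1.0)
  expect_equal(bonferroni(c(0.001, 0.02), m = 8), c(0.008, 0.16))
  p <- c(0.001, 0.004, 0.04)
  expect_identical(order(bonferroni(p, 10)), order(p))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
  expect_error(bonferroni(1.2), "pvals")
})

test_that("correlations match the closed-form coefficient", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y <- c(2.0, 3.1, 2.4, 6.2, 3.9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate(x, y)$r, r_hand, tolerance = 1e-12)
  expect_equal(correlate(x, 2 * x)$r, 1)
  xm <- 1:20
  ym <- exp(xm / 4)                            # monotone, nonlinear
  expect_equal(correlate(xm, ym, "spearman")$r, 1)
  expect_lt(correlate(xm, ym, "pearson")$r, 1)
  expect_error(correlate(x, rep(1, 5)), "zero variance")
  expect_error(correlate(1:3, 3:1), "at least 4")
})

test_that("standardized regression has the OLS identities", {
  set.seed(46)
  n <- 100
  d <- data.frame(x = rnorm(n))
  d$y <- 0.6 * d$x + rnorm(n)
  fit <- multiple_regression(d, "y", "x", controlled = character(0))
  expect_equal(unname(fit$beta["x"]), correlate(d$x, d$y)$r, tolerance = 1e-10)

  # n = 35 with 5 total predictors: df (5, 29)
  pre <- cohort_preset_default(35)
  co <- generate_cohort(pre, seed = 47)
  sz <- co[co$group == "SZ", ]
  f2 <- multiple_regression(sz, "tau",
                            c("bc_posterior_gamma", "bc_max_gamma"))
  expect_identical(f2$df, c(5L, 29L))

  # generative recovery: the planted r = 0.72 predictor dominates
  big <- generate_cohort(cohort_preset_default(2000), seed = 48)
  szb <- big[big$group == "SZ", ]
  f3 <- multiple_regression(szb, "tau",
                            c("bc_posterior_gamma", "bc_max_gamma"))
  expect_identical(names(which.max(abs(f3$beta))), "bc_posterior_gamma")
  expect_equal(unname(f3$beta["bc_posterior_gamma"]), 0.72, tolerance = 0.05)

  szb$dup2 <- szb$dup                          # exact duplicate column
  expect_error(multiple_regression(szb, "tau", c("bc_posterior_gamma", "dup2")),
               "collinear column")
})

test_that("KS normality statistic equals the direct max-gap computation", {
  set.seed(49)
  x <- round(rnorm(20, 100, 15), 1)
  res <- ks_normality(x)
  xs <- sort(x)
  Fhat <- pnorm(xs, mean(x), sd(x))
  D_hand <- max(pmax(seq_along(xs) / 20 - Fhat, Fhat - (seq_along(xs) - 1) / 20))
  expect_equal(res$D, D_hand, tolerance = 1e-12)
  expect_gt(ks_normality(rnorm(2000))$p, 0.1)
  expect_lt(ks_normality(rexp(2000))$p, 0.01)
  expect_error(ks_normality(rep(3, 10)), "zero variance")
})

test_that("null cohorts reject at the nominal rate before correction", {
  set.seed(50)
  rejections <- vapply(1:300, function(i) {
    d <- data.frame(group = factor(rep(c("HC", "SZ"), each = 35)),
                    age = rnorm(70, 21, 2), education = rnorm(70, 14, 1.5),
                    premorbid_iq = rnorm(70, 107, 7), y = rnorm(70))
    ancova_group_effect(d, "y")$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.04)  # ~3 MC sigma, absolute
})
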