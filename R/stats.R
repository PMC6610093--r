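# Group-statistics layer: transforms, covariate-adjusted comparisons with
# partial eta squared, Bonferroni control, correlations, standardized
# multiple regression, and a normality check.

#' Natural-log transform with small-offset zero protection
#'
#' `ln(x + 1e-24)`: the offset keeps exact zeros finite while being far
#' below measurement precision for any nonzero metric.
#'
#' @param x non-negative numeric.
#' @param eps offset, default `1e-24`.
#' @return `log(x + eps)`.
#' @export
log_transform <- function(x, eps = 1e-24) {
  if (any(x < 0, na.rm = TRUE)) stop("log_transform requires non-negative input")
  log(x + eps)
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Ordinary least squares of `outcome ~ group + covariates`; the group
#' effect is the F for dropping the group term from the full model, with
#' partial eta squared `SS_group / (SS_group + SS_error)` and degrees of
#' freedom `(1, n - p - 1)` where `p` counts the group indicator plus
#' covariates.  With a single two-level factor and covariates always
#' retained, Type I/II/III sums of squares coincide for the group term.
#'
#' @param data data frame.
#' @param outcome outcome column name (numeric).
#' @param group two-level factor column name.
#' @param covariates covariate column names (numeric), default age,
#'   education and premorbid IQ.
#' @return List of class `group_effect`: `F`, `df` (numerator,
#'   denominator), `p`, `eta_p_sq`, `direction` (sign of the adjusted
#'   difference, second factor level minus first), `n`.
#' @export
ancova_group_effect <- function(data, outcome, group = "group",
                                covariates = c("age", "education",
                                               "premorbid_iq")) {
  cols <- c(outcome, group, covariates)
  stopifnot(all(cols %in% names(data)))
  d <- data[complete.cases(data[cols]), cols, drop = FALSE]
  d[[group]] <- droplevels(factor(d[[group]]))
  if (nlevels(d[[group]]) != 2L)
    stop("group must have exactly 2 levels with data, got ",
         nlevels(d[[group]]))
  if (any(table(d[[group]]) < 2L)) stop("need at least 2 subjects per group")
  if (nrow(d) - length(covariates) - 2L < 1L)
    stop("need more observations (", nrow(d), ") than predictors (",
         length(covariates) + 1L, ") plus intercept")
  rhs_cov <- paste(covariates, collapse = " + ")
  full <- lm(as.formula(paste(outcome, "~", group,
                              if (length(covariates)) paste("+", rhs_cov))),
             data = d)
  if (anyNA(coef(full)))
    stop("collinear predictors: ",
         paste(names(coef(full))[is.na(coef(full))], collapse = ", "))
  reduced <- lm(as.formula(paste(outcome, "~",
                                 if (length(covariates)) rhs_cov else "1")),
                data = d)
  rss_full <- sum(residuals(full)^2)
  ss_group <- sum(residuals(reduced)^2) - rss_full
  n <- nrow(d)
  p <- 1L + length(covariates)
  df2 <- n - p - 1L
  Fval <- (ss_group / 1) / (rss_full / df2)
  grp_coef <- coef(full)[grep(paste0("^", group), names(coef(full)))][1L]
  structure(list(F = Fval, df = c(1L, df2), p = pf(Fval, 1L, df2,
                                                   lower.tail = FALSE),
                 eta_p_sq = ss_group / (ss_group + rss_full),
                 direction = sign(unname(grp_coef)), n = n),
            class = "group_effect")
}

#' @export
print.group_effect <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.2f, p = %.4g, eta_p^2 = %.3f\n",
              x$df[1L], x$df[2L], x$F, x$p, x$eta_p_sq))
  invisible(x)
}

#' Bonferroni correction
#'
#' @param pvals p-values in \[0, 1\].
#' @param m family size; must be at least `length(pvals)`.
#' @return `pmin(1, pvals * m)`.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  if (m < length(pvals))
    stop("family size m (", m, ") smaller than number of tests (",
         length(pvals), ")")
  pmin(1, pvals * m)
}

#' Pearson or Spearman correlation with two-tailed p
#'
#' @param x,y equal-length numeric vectors, `n >= 4`.
#' @param method `"pearson"` or `"spearman"` (midrank ties).
#' @return List with `r`, `p`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}

#' Standardized multiple regression
#'
#' OLS on the z-scored outcome and predictors, so coefficients are
#' standardized betas; reports `R^2` and the overall F with df
#' `(k, n - k - 1)`.  Controlled clinical predictors enter the model like
#' any other predictor but are reported separately.
#'
#' @param data data frame.
#' @param outcome outcome column name.
#' @param predictors predictor column names of interest.
#' @param controlled additional controlled predictor column names (default
#'   the illness-duration / DUP / medication triple).
#' @return List of class `regression_result`: `beta` (named, predictors
#'   then controlled), `r_squared`, `F`, `df`, `p`, `n`.
#' @export
multiple_regression <- function(data, outcome, predictors,
                                controlled = c("duration_of_illness", "dup",
                                               "risperidone_eq")) {
  allp <- c(predictors, controlled)
  cols <- c(outcome, allp)
  stopifnot(all(cols %in% names(data)))
  d <- data[complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  k <- length(allp)
  if (n <= k + 1L) stop("need more observations (", n, ") than predictors (",
                        k, ") plus intercept")
  z <- as.data.frame(lapply(d, function(col) {
    s <- sd(col)
    if (s == 0) stop("zero-variance column")
    (col - mean(col)) / s
  }))
  fit <- lm(as.formula(paste(outcome, "~", paste(allp, collapse = " + "))),
            data = z)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  rss <- sum(residuals(fit)^2)
  tss <- sum(z[[outcome]]^2)
  r2 <- 1 - rss / tss
  df2 <- n - k - 1L
  Fval <- (r2 / k) / ((1 - r2) / df2)
  structure(list(beta = cf[-1L], r_squared = r2, F = Fval,
                 df = c(k, df2), p = pf(Fval, k, df2, lower.tail = FALSE),
                 n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("R^2 = %.2f, F(%d, %d) = %.2f, p = %.4g\n",
              x$r_squared, x$df[1L], x$df[2L], x$F, x$p))
  b <- sort(abs(x$beta), decreasing = TRUE)
  cat("standardized betas:",
      paste(sprintf("%s = %.2f", names(b), x$beta[names(b)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic against a normal with the sample mean and SD.
#' Because the reference parameters are estimated from the same data, the
#' p-value is conservative-leaning (the Lilliefors caveat); it is used here
#' as the conventional screen before parametric modelling.
#'
#' @param x numeric vector, `n >= 5`.
#' @return List with `D` and `p`.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5L) stop("need at least 5 observations")
  if (sd(x) == 0) stop("zero variance input")
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  list(D = unname(kt$statistic), p = kt$p.value)
}
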