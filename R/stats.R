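#' Correlation with bootstrap confidence interval
#'
#' Pearson or Spearman correlation with a p-value from the t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} and a 95% confidence interval from
#' seeded paired bootstrap resampling (percentile interval by default, 1000
#' resamples — the convention of the cohort analyses this package supports;
#' bias-corrected-accelerated optionally).
#'
#' @param x,y numeric vectors, equal length `n >= 4`, no missing values.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param n_boot bootstrap resamples for the CI (default 1000; 0 skips the
#'   CI).
#' @param seed integer seed for the resampling (isolated RNG scope).
#' @param conf confidence level (default 0.95).
#' @param ci_type `"percentile"` (default) or `"bca"`.
#' @return A `cor_boot` object: `r`, `p`, `ci_low`, `ci_high`, `method`,
#'   `n`, `n_boot`, `seed`.
#' @examples
#' set.seed(1)
#' x <- rnorm(40); y <- 0.5 * x + rnorm(40)
#' correlate(x, y, seed = 1)
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      n_boot = 1000, seed = 1L, conf = 0.95,
                      ci_type = c("percentile", "bca")) {
  method <- match.arg(method)
  ci_type <- match.arg(ci_type)
  check_xy(x, y)
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  r <- stats::cor(x, y, method = method)
  p <- cor_p_from_t(r, n)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    rb <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
        stats::cor(x[i], y[i], method = method)
      }, numeric(1))
    })
    rb <- rb[is.finite(rb)]
    a <- (1 - conf) / 2
    if (ci_type == "percentile") {
      ci <- unname(stats::quantile(rb, c(a, 1 - a)))
    } else {
      z0 <- stats::qnorm(mean(rb < r))
      jack <- vapply(seq_len(n), function(i) {
        stats::cor(x[-i], y[-i], method = method)
      }, numeric(1))
      jm <- mean(jack)
      num <- sum((jm - jack)^3)
      den <- 6 * sum((jm - jack)^2)^1.5
      acc <- if (den == 0) 0 else num / den
      za <- stats::qnorm(c(a, 1 - a))
      adj <- stats::pnorm(z0 + (z0 + za) / (1 - acc * (z0 + za)))
      ci <- unname(stats::quantile(rb, adj))
    }
  }
  structure(
    list(r = r, p = p, ci_low = ci[1], ci_high = ci[2], method = method,
         n = n, n_boot = n_boot, seed = seed),
    class = "cor_boot"
  )
}

check_xy <- function(x, y, min_n = 4L) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < min_n) stop("need n >= ", min_n)
  if (anyNA(x) || anyNA(y)) stop("missing values are not accepted")
  invisible(TRUE)
}

cor_p_from_t <- function(r, n, df = n - 2) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

#' @export
print.cor_boot <- function(x, digits = 3, ...) {
  cat(sprintf("%s correlation%s: r = %.*f (%.*f, %.*f), p = %.3g, n = %d\n",
              tools::toTitleCase(sub("partial_", "partial ", x$method)),
              if (x$n_boot > 0) sprintf(" (%d bootstrap resamples)", x$n_boot)
              else "",
              digits, x$r, digits, x$ci_low, digits, x$ci_high, x$p, x$n))
  invisible(x)
}

#' Partial correlation controlling for covariates
#'
#' Pearson (or Spearman, via ranks) correlation of the residuals of `x` and
#' `y` after each is regressed (with intercept) on the covariates — e.g. a
#' release-vs-Ki correlation corrected for individual differences in body
#' weight under a fixed drug amount. The p-value uses `df = n - 2 - k` for
#' `k` covariates; the bootstrap CI resamples complete rows.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector, matrix or data frame of covariates.
#' @param method `"pearson"` or `"spearman"` (ranks taken before
#'   residualising).
#' @inheritParams correlate
#' @return A `cor_boot` object with method `"partial_<method>"`.
#' @export
partial_correlate <- function(x, y, covariates,
                              method = c("pearson", "spearman"),
                              n_boot = 1000, seed = 1L, conf = 0.95) {
  method <- match.arg(method)
  Z <- as.matrix(covariates)
  check_xy(x, y, min_n = ncol(Z) + 4L)
  if (nrow(Z) != length(x)) stop("covariate length mismatch")
  if (anyNA(Z)) stop("missing values are not accepted")
  k <- ncol(Z)
  n <- length(x)
  pr <- function(x, y, Z) {
    if (method == "spearman") {
      x <- rank(x); y <- rank(y); Z <- apply(Z, 2, rank)
    }
    rx <- stats::lm.fit(cbind(1, Z), x)$residuals
    ry <- stats::lm.fit(cbind(1, Z), y)$residuals
    if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1) ||
        stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1)) {
      stop("zero residual variance (covariate collinear with x or y)")
    }
    stats::cor(rx, ry)
  }
  r <- pr(x, y, Z)
  p <- cor_p_from_t(r, n, df = n - 2 - k)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    rb <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        tryCatch(pr(x[i], y[i], Z[i, , drop = FALSE]),
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    rb <- rb[is.finite(rb)]
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(rb, c(a, 1 - a)))
  }
  structure(
    list(r = r, p = p, ci_low = ci[1], ci_high = ci[2],
         method = paste0("partial_", method), n = n, n_boot = n_boot,
         seed = seed),
    class = "cor_boot"
  )
}

#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test and labels the sample `"normal"` or
#' `"non_normal"` at level `alpha` — the gate deciding whether downstream
#' correlations use Pearson or fall back to Spearman.
#'
#' @param x numeric sample, `3 <= n <= 5000`, non-constant.
#' @param alpha gate level (default 0.05; `alpha = 0` always passes).
#' @return A list: `verdict` (`"normal"`/`"non_normal"`), `W`, `p`.
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  if (length(unique(x)) < 2L) stop("constant input")
  ht <- stats::shapiro.test(x)
  list(
    verdict = if (ht$p.value < alpha) "non_normal" else "normal",
    W = unname(ht$statistic), p = ht$p.value
  )
}

#' Paired t-test with Cohen's dz
#'
#' Two-tailed paired t-test on `a - b` with the paired-samples effect size
#' \eqn{d_z = \bar d / s_d = t / \sqrt{n}}.
#'
#' @param a,b paired numeric vectors, `n >= 2`.
#' @return A `paired_ttest` list: `t`, `df`, `p`, `dz`, `mean_diff`, `n`.
#' @examples
#' paired_ttest(c(2, 3, 4), c(1, 1, 1)) # t = 3.464, dz = 2
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b lengths differ")
  n <- length(a)
  if (n < 2L) stop("need n >= 2")
  if (anyNA(a) || anyNA(b)) stop("missing values are not accepted")
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("zero standard deviation of differences")
  t <- mean(d) / (sd_d / sqrt(n))
  structure(
    list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1),
         dz = mean(d) / sd_d, mean_diff = mean(d), n = n),
    class = "paired_ttest"
  )
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("Paired t-test: t(%d) = %.3f, p = %.3g, dz = %.2f\n",
              x$df, x$t, x$p, x$dz))
  invisible(x)
}

#' Cohen's dz from a reported paired t statistic
#'
#' The identity \eqn{d_z = t / \sqrt{n}} recovers the paired-samples effect
#' size from a printed t value and sample size.
#'
#' @param t paired t statistic.
#' @param n number of pairs.
#' @return `dz`.
#' @examples
#' dz_from_t(1.08, 40) # ~0.17
#' @export
dz_from_t <- function(t, n) {
  stopifnot(n >= 1)
  t / sqrt(n)
}

#' Ordinary least squares multiple regression
#'
#' OLS with intercept: per-coefficient t and p, overall F with its p, and
#' adjusted r^2 — the regression battery used to test whether post-drug
#' binding is explained by baseline binding, synthesis capacity, and region
#' volume.
#'
#' @param y response vector.
#' @param predictors matrix or data frame of predictors, full column rank,
#'   `n > p + 1`.
#' @return A `reg_result` list: `coefficients` (data frame with estimate,
#'   se, t, p per term), `F`, `p`, `r_squared`, `adj_r_squared`, `df`.
#' @export
ols_regression <- function(y, predictors) {
  X <- as.data.frame(predictors)
  n <- length(y)
  if (nrow(X) != n) stop("predictor length mismatch")
  if (n <= ncol(X) + 1L) stop("need n > number of predictors + 1")
  if (anyNA(y) || anyNA(X)) stop("missing values are not accepted")
  fit <- stats::lm(y ~ ., data = cbind(y = y, X))
  if (anyNA(stats::coef(fit))) stop("rank-deficient predictor matrix")
  s <- summary(fit)
  co <- as.data.frame(s$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  fstat <- s$fstatistic
  structure(
    list(
      coefficients = co,
      F = unname(fstat[1]),
      p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
      r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
      df = unname(fstat[2:3]), lm = fit
    ),
    class = "reg_result"
  )
}

#' @export
print.reg_result <- function(x, digits = 3, ...) {
  cat(sprintf("OLS regression: F(%d, %d) = %.3f, p = %.3g, adj r^2 = %.3f\n",
              x$df[1], x$df[2], x$F, x$p, x$adj_r_squared))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Power of a correlation test (Fisher-z approximation)
#'
#' Power of the test of `H0: rho = 0` at sample size `n`, or the smallest
#' `n` achieving `target_power`, using the Fisher-z approximation
#' \eqn{power = \Phi(|z(\rho)| \sqrt{n-3} - z_{crit})} (plus the negligible
#' opposite tail for two-tailed tests). This differs slightly from exact
#' bivariate-normal routines.
#'
#' @param n sample size (`NULL` when solving for `min_n`).
#' @param rho true correlation in `(-1, 1)`, nonzero when a target power
#'   above `alpha` is requested.
#' @param alpha test level (default 0.05).
#' @param tails 1 or 2 (default 2).
#' @param target_power power to achieve (`NULL` when computing power at `n`).
#' @return `power` (when `n` given) or `min_n` (when `target_power` given).
#' @examples
#' correlation_power(n = 40, rho = 0.43) # ~0.80
#' @export
correlation_power <- function(n = NULL, rho, alpha = 0.05, tails = 2,
                              target_power = NULL) {
  stopifnot(abs(rho) < 1, tails %in% c(1, 2))
  if (is.null(n) == is.null(target_power)) {
    stop("supply exactly one of n and target_power")
  }
  pw <- function(n) {
    if (n < 4) return(NA_real_)
    zc <- stats::qnorm(1 - alpha / tails)
    za <- abs(atanh(rho)) * sqrt(n - 3)
    p <- stats::pnorm(za - zc)
    if (tails == 2) p <- p + stats::pnorm(-za - zc)
    p
  }
  if (!is.null(n)) {
    if (rho == 0) return(alpha)
    return(pw(n))
  }
  if (rho == 0 && target_power > alpha) {
    stop("rho = 0 cannot reach power above alpha")
  }
  n <- 4
  while (pw(n) < target_power) n <- n + 1
  n
}

#' Bonferroni significance flags
#'
#' Flags `p_i < alpha / m` for a family of `m` comparisons.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param m number of comparisons, `>= 1` (default: `length(p_values)`).
#' @param alpha family-wise level (default 0.05).
#' @return Logical vector.
#' @examples
#' bonferroni_flags(c(0.008, 0.031), m = 3) # TRUE FALSE
#' @export
bonferroni_flags <- function(p_values, m = length(p_values), alpha = 0.05) {
  if (m < 1) stop("m must be >= 1")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]")
  }
  p_values < alpha / m
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation from the standard ANOVA decomposition:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' with `n` targets, `k` raters, row (target), column (rater) and error mean
#' squares. Used for inter-rater reliability of region values.
#'
#' @param ratings numeric matrix or data frame, one row per target, one
#'   column per rater, complete (no missing values).
#' @return The ICC(2,1) coefficient.
#' @export
icc <- function(ratings) {
  m <- as.matrix(ratings)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 targets and >= 2 raters")
  if (anyNA(m)) stop("ratings must be complete")
  if (stats::sd(as.numeric(m)) == 0) stop("constant ratings table")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_e <- ss_tot - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
}
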