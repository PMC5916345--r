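test_that("correlation point estimate matches the closed-form ratio", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0, 6.3, 7.7, 8.1, 9.9, 10.4)
  y <- c(2.0, 1.8, 3.9, 4.1, 6.2, 5.8, 7.9, 9.0, 8.8, 11.1)
  res <- correlate(x, y, n_boot = 0)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, oracle, tolerance = 1e-12)
  expect_equal(res$p, stats::cor.test(x, y)$p.value, tolerance = 1e-12)
  # exact linear relation: r = 1 with a degenerate CI
  lin <- correlate(x, 2 * x + 1, n_boot = 200, seed = 3)
  expect_equal(lin$r, 1)
  expect_equal(c(lin$ci_low, lin$ci_high), c(1, 1))
  expect_error(correlate(x, rep(1, 10), n_boot = 0), "zero variance")
})

test_that("bootstrap CIs are seed-reproducible and tighten with n", {
  set.seed(42)
  x <- stats::rnorm(40); y <- 0.6 * x + stats::rnorm(40, sd = 0.8)
  a <- correlate(x, y, n_boot = 500, seed = 9)
  b <- correlate(x, y, n_boot = 500, seed = 9)
  expect_identical(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high))
  widths <- vapply(c(20, 80, 320), function(n) {
    xi <- withr::with_seed(100 + n, stats::rnorm(n))
    yi <- withr::with_seed(200 + n, 0.5 * xi + stats::rnorm(n, sd = 0.9))
    r <- correlate(xi, yi, n_boot = 400, seed = 1)
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # BCa variant returns an ordered interval containing sensible values
  bca <- correlate(x, y, n_boot = 500, seed = 9, ci_type = "bca")
  expect_lt(bca$ci_low, bca$ci_high)
})

test_that("Pearson/Spearman invariances hold", {
  set.seed(7)
  x <- stats::rnorm(30); y <- x + stats::rnorm(30)
  p1 <- correlate(x, y, n_boot = 0)$r
  p2 <- correlate(3 * x + 5, 0.2 * y - 1, n_boot = 0)$r
  expect_equal(p2, p1, tolerance = 1e-12)
  s1 <- correlate(x, y, method = "spearman", n_boot = 0)$r
  s2 <- correlate(exp(x), y^3 + 2 * y, method = "spearman", n_boot = 0)$r
  expect_equal(s2, s1, tolerance = 1e-12)
})

test_that("Pearson test holds its type-I error rate under the null", {
  n <- 40
  rejections <- withr::with_seed(1, {
    vapply(seq_len(2000), function(i) {
      correlate(stats::rnorm(n), stats::rnorm(n), n_boot = 0)$p < 0.05
    }, logical(1))
  })
  expect_gte(mean(rejections), 0.04)
  expect_lte(mean(rejections), 0.06)
})

test_that("partial correlation residualizes correctly", {
  set.seed(11)
  x <- stats::rnorm(50); y <- stats::rnorm(50); zr <- stats::rnorm(50)
  # force the covariate to be exactly orthogonal to x and y
  z <- stats::lm.fit(cbind(1, x, y), zr)$residuals
  expect_equal(partial_correlate(x, y, z, n_boot = 0)$r,
               correlate(x, y, n_boot = 0)$r, tolerance = 1e-12)
  # matches the closed-form partial-correlation formula
  w <- 0.5 * x + stats::rnorm(50)
  v <- -0.3 * x + stats::rnorm(50)
  rxy <- stats::cor(w, v); rxz <- stats::cor(w, x); ryz <- stats::cor(v, x)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partial_correlate(w, v, x, n_boot = 0)$r, oracle,
               tolerance = 1e-10)
  expect_error(partial_correlate(x, y, x, n_boot = 0), "zero residual")
})

test_that("Shapiro-Wilk gate routes distributions correctly", {
  g1 <- shapiro_gate(withr::with_seed(1, stats::rnorm(40)))
  expect_equal(g1$verdict, "normal")
  g2 <- shapiro_gate(withr::with_seed(2, stats::rexp(200)))
  expect_equal(g2$verdict, "non_normal")
  expect_equal(shapiro_gate(withr::with_seed(2, stats::rexp(200)),
                            alpha = 0)$verdict, "normal")
  expect_error(shapiro_gate(rep(1, 10)), "constant")
})

test_that("paired t-test and Cohen's dz", {
  res <- paired_ttest(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$dz, 2)
  expect_equal(res$df, 2L)
  expect_equal(res$p, stats::t.test(c(1, 2, 3))$p.value, tolerance = 1e-12)
  # zero-mean differences give t = 0
  b <- c(5, 6, 7, 8)
  res0 <- paired_ttest(b + c(-1, 1, -1, 1), b)
  expect_equal(res0$t, 0)
  expect_equal(res0$dz, 0)
  expect_error(paired_ttest(b, b), "zero standard deviation")
  # recovering dz from a printed t statistic
  expect_equal(round(dz_from_t(1.08, 40), 2), 0.17)
  expect_equal(paired_ttest(c(1, 2, 3), c(0, 0, 0))$dz,
               dz_from_t(res$t, 3), tolerance = 1e-12)
})

test_that("OLS regression matches the normal-equation oracle", {
  set.seed(5)
  X <- data.frame(a = stats::rnorm(8), b = stats::rnorm(8))
  y <- 1 + 2 * X$a - 0.5 * X$b + stats::rnorm(8, sd = 0.3)
  res <- ols_regression(y, X)
  Xm <- cbind(1, as.matrix(X))
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
  expect_equal(res$coefficients$estimate, as.numeric(beta),
               tolerance = 1e-10)
  expect_lte(res$adj_r_squared, res$r_squared)
  # exact linear response (lm warns about the perfect fit; that is the point)
  exact <- suppressWarnings(ols_regression(1 + 2 * X$a - 0.5 * X$b, X))
  expect_equal(exact$adj_r_squared, 1, tolerance = 1e-10)
  # predictor order permutes coefficients identically
  res2 <- ols_regression(y, X[, c("b", "a")])
  expect_equal(res2$coefficients["a", "estimate"],
               res$coefficients["a", "estimate"], tolerance = 1e-12)
  expect_error(ols_regression(y, data.frame(a = X$a, a2 = X$a)), "rank")
})

test_that("correlation power follows the Fisher-z formula", {
  expect_equal(correlation_power(n = 40, rho = 0), 0.05)
  p <- correlation_power(n = 40, rho = 0.43)
  zc <- stats::qnorm(0.975)
  za <- atanh(0.43) * sqrt(37)
  expect_equal(p, stats::pnorm(za - zc) + stats::pnorm(-za - zc),
               tolerance = 1e-12)
  expect_equal(p, 0.80, tolerance = 0.01)
  ns <- vapply(c(0.2, 0.3, 0.4, 0.6), function(r) {
    correlation_power(rho = r, target_power = 0.8)
  }, numeric(1))
  expect_true(all(diff(ns) < 0))
  expect_error(correlation_power(rho = 0, target_power = 0.8), "rho = 0")
  expect_error(correlation_power(n = 10, rho = 0.3, target_power = 0.8),
               "exactly one")
})

test_that("Bonferroni flags a three-comparison family correctly", {
  expect_true(bonferroni_flags(0.008, m = 3))
  expect_false(bonferroni_flags(0.031, m = 3))
  expect_equal(bonferroni_flags(c(0.04, 0.06), m = 1), c(TRUE, FALSE))
  expect_error(bonferroni_flags(1.2, 1), "0, 1")
})

test_that("ICC(2,1) matches an aov mean-squares oracle", {
  ratings <- matrix(c(9.1, 8.7, 9.3,
                      7.2, 7.5, 7.1,
                      6.4, 6.1, 6.6,
                      8.8, 9.0, 8.5,
                      5.5, 5.9, 5.3), 5, 3, byrow = TRUE)
  got <- icc(ratings)
  d <- data.frame(
    y = as.numeric(ratings),
    target = factor(rep(1:5, 3)),
    rater = factor(rep(1:3, each = 5))
  )
  ms <- summary(stats::aov(y ~ target + rater, data = d))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  oracle <- (msr - mse) / (msr + 2 * mse + 3 * (msc - mse) / 5)
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_equal(icc(cbind(1:6, 1:6, 1:6)), 1, tolerance = 1e-12)
  # absolute agreement: a constant rater offset lowers ICC(2,1)
  shifted <- ratings; shifted[, 2] <- shifted[, 2] + 1.5
  expect_lt(icc(shifted), got)
  expect_error(icc(matrix(1, 4, 3)), "constant")
})
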