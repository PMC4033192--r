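test_that("normality_test branches on the Shapiro-Wilk p-value", {
  set.seed(108)  # a seed whose normal draw is comfortably non-boundary
  x <- rnorm(50)
  expect_equal(normality_test(x), "normal")
  expect_equal(stats::shapiro.test(x)$p.value > 0.05, TRUE)  # oracle agrees
  y <- exp(rnorm(50, 0, 1))
  expect_equal(normality_test(y), "non_normal")
  expect_warning(res <- normality_test(rep(1, 10)), "constant")
  expect_equal(res, "non_normal")
  expect_error(normality_test(c(1, 2)), "at least 3")
})

test_that("site_anova matches hand sums of squares", {
  r <- site_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r$F, 0)

  # groups (1,2) vs (5,6): SSB = 16, SSW = 1 -> F = (16/1)/(1/2) = 32
  r2 <- site_anova(c(1, 2, 5, 6), c("a", "a", "b", "b"))
  expect_equal(r2$F, 32)
  expect_equal(r2$p, stats::pf(32, 1, 2, lower.tail = FALSE))
  expect_equal(r2$df, c(1, 2))

  # textbook formula oracle on three random groups
  set.seed(102)
  g <- rep(c("x", "y", "z"), c(5, 7, 6))
  v <- rnorm(18, mean = c(x = 0, y = 1, z = 0.5)[g])
  r3 <- site_anova(v, g)
  gm <- mean(v); ssb <- sum(tapply(v, g, function(u) length(u) * (mean(u) - gm)^2))
  ssw <- sum(tapply(v, g, function(u) sum((u - mean(u))^2)))
  expect_equal(r3$F, (ssb / 2) / (ssw / 15), tolerance = 1e-10)

  expect_error(site_anova(1:4, rep("a", 4)), "at least 2 sites")
})

test_that("ancova_gender produces Type-II F tests and an interaction increment", {
  # identical noiseless line in both genders -> zero interaction exactly
  x <- c(1:6, 1:6)
  g <- rep(c("male", "female"), each = 6)
  y <- 2 * x + 1
  r <- suppressWarnings(ancova_gender(y, x, g))
  expect_lt(r$F_interaction, 1e-9)

  # constructed 8-point dataset vs model-comparison oracle via anova()
  set.seed(103)
  x8 <- c(1, 2, 3, 4, 1.5, 2.5, 3.5, 4.5)
  g8 <- rep(c("male", "female"), each = 4)
  y8 <- c(2, 3, 5, 6, 1, 4, 4, 7) + 0.1 * x8
  r8 <- ancova_gender(y8, x8, g8)
  gf <- factor(g8)
  full <- lm(y8 ~ gf * x8); main <- lm(y8 ~ gf + x8)
  mse <- sum(residuals(full)^2) / full$df.residual
  f_int_oracle <- anova(main, full)$F[2]
  expect_equal(r8$F_interaction, f_int_oracle, tolerance = 1e-10)
  f_g_oracle <- (sum(residuals(lm(y8 ~ x8))^2) -
                 sum(residuals(main)^2)) / mse
  f_v_oracle <- (sum(residuals(lm(y8 ~ gf))^2) -
                 sum(residuals(main)^2)) / mse
  expect_equal(r8$F_gender, f_g_oracle, tolerance = 1e-10)
  expect_equal(r8$F_value, f_v_oracle, tolerance = 1e-10)
  expect_equal(r8$n, 8)

  expect_warning(rc <- ancova_gender(y8, rep(2, 8), g8), "constant")
  expect_true(is.na(rc$F_value))
  expect_error(ancova_gender(y8, x8, rep("male", 8)), "both genders")
})

test_that("pls_regression agrees with correlation and OLS oracles", {
  set.seed(104)
  x <- rnorm(25); y <- 1.5 * x + rnorm(25, 0, 0.7)
  r1 <- pls_regression(matrix(x, ncol = 1, dimnames = list(NULL, "m")),
                       y, n_components = 1)
  expect_equal(r1$r_squared, cor(x, y)^2, tolerance = 1e-10)

  X <- matrix(rnorm(48), 12, 4, dimnames = list(NULL, paste0("m", 1:4)))
  yy <- as.vector(X %*% c(1, -2, 0.5, 0)) + rnorm(12, 0, 0.5)
  r4 <- pls_regression(X, yy, n_components = 4)
  ols <- summary(lm(yy ~ X))$r.squared
  expect_equal(r4$r_squared, ols, tolerance = 1e-8)

  # R^2 non-decreasing in component count; VIP mean-square is 1
  r2s <- vapply(1:4, function(a)
    pls_regression(X, yy, n_components = a)$r_squared, numeric(1))
  expect_true(all(diff(r2s) >= -1e-10))
  expect_equal(mean(r4$vip^2), 1, tolerance = 1e-6)

  expect_warning(rc <- pls_regression(X, rep(3, 12)), "constant response")
  expect_equal(rc$r_squared, 0)
  expect_true(all(is.na(rc$vip)))
  expect_error(pls_regression(X[1:2, ], yy[1:2]), "at least 3")
})

test_that("adjusted_correlation residualizes exactly and falls back to plain r", {
  set.seed(105)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40, 0, 0.5)
  plain <- adjusted_correlation(x, y, covariates = NULL)
  expect_equal(plain$r, cor(x, y), tolerance = 1e-12)
  expect_equal(plain$method, "pearson")

  # y = x + site offset; site dummies absorb the offset exactly
  site <- rep(c("s1", "s2", "s3", "s4"), each = 10)
  y2 <- x + c(s1 = 0, s2 = 5, s3 = -3, s4 = 9)[site]
  r2 <- adjusted_correlation(x, y2, covariates = data.frame(site = site))
  expect_equal(r2$r, 1, tolerance = 1e-9)

  # 6-point toy with one covariate vs lm-residual oracle
  x6 <- c(1, 2, 3, 4, 5, 6.5); y6 <- c(2, 1, 4, 3, 6, 5)
  cv <- c(0.4, 1.1, 1.9, 3.2, 3.8, 5.1)
  r6 <- adjusted_correlation(x6, y6, covariates = data.frame(cv = cv),
                             method = "pearson")
  expect_equal(r6$r, cor(residuals(lm(x6 ~ cv)), residuals(lm(y6 ~ cv))),
               tolerance = 1e-10)
  expect_equal(r6$df, 6 - 2 - 1)

  # invariance to affine covariate rescaling
  r6b <- adjusted_correlation(x6, y6,
                              covariates = data.frame(cv = 100 * cv - 7),
                              method = "pearson")
  expect_equal(r6$r, r6b$r, tolerance = 1e-10)

  expect_error(
    adjusted_correlation(x, y, covariates = data.frame(a = 1:40, b = 1:40)),
    "collinear")
})

test_that("quartile_contrast splits by type-7 quantiles and reports |diff|", {
  r <- quartile_contrast(1:8, 1:8, marker = "toy")
  # Q1 = 2.75, Q3 = 6.25 -> groups {1,2} and {7,8}
  expect_equal(r$n1, 2); expect_equal(r$n4, 2)
  expect_equal(r$mean1, 1.5); expect_equal(r$mean4, 7.5)
  expect_equal(r$abs_diff, 6)

  r0 <- suppressWarnings(quartile_contrast(rep(2, 12), 1:12))
  expect_equal(r0$abs_diff, 0)

  expect_error(quartile_contrast(1:4, 1:4), "at least 8")
  expect_error(quartile_contrast(1:8, rep(1, 8)), "degenerate")
})

test_that("holm_adjust matches the step-down definition and p.adjust", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.06, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))

  set.seed(106)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "holm"))        # reference oracle
    expect_true(all(adj >= p))                           # never smaller
    expect_true(all(adj <= pmin(length(p) * p, 1) + 1e-12))  # <= Bonferroni
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("combined_group_split honors inclusive medians and the flip set", {
  rec <- data.frame(a = c(1, 1, 1), b = c(2, 2, 2))
  s <- combined_group_split(rec, c("a", "b"))
  expect_true(all(s$healthy) && all(s$risky) && all(s$both))

  # correlated markers (medians a = 2.5, b = 2.5): brute-force enumeration
  rec4 <- data.frame(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
  s4 <- combined_group_split(rec4, c("a", "b"))
  expect_equal(s4$healthy, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(s4$risky, c(FALSE, FALSE, TRUE, TRUE))
  expect_false(any(s4$both))

  # flipped marker: above-median b is healthy
  rec4f <- data.frame(a = c(1, 2, 3, 4), b = c(3, 4, 1, 2))
  s4f <- combined_group_split(rec4f, c("a", "b"), flip = "b")
  expect_equal(s4f$healthy, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(s4f$risky, c(FALSE, FALSE, TRUE, TRUE))
  # anticorrelated markers with no qualifying subject are degenerate
  expect_error(combined_group_split(rec4f, c("a", "b")), "degenerate")

  expect_error(combined_group_split(rec4, c("a", "zz")), "missing marker")
  expect_error(combined_group_split(rec4, "a", flip = "b"), "subset")
})

test_that("compare_groups branches between t and Mann-Whitney", {
  g <- c(1, 2, 3, 4, 5)
  r <- suppressWarnings(compare_groups(g, g))
  expect_equal(r$p, 1, tolerance = 1e-12)
  expect_equal(r$statistic, 0, tolerance = 1e-12)

  set.seed(107)
  a <- rnorm(6, 0, 1e-3); b <- rnorm(6, 5, 1e-3)
  expect_lt(suppressWarnings(compare_groups(a, b))$p, 1e-6)

  # 5v5 pooled-variance t statistic by hand
  x <- c(1.2, 2.4, 1.8, 2.0, 1.6); y <- c(2.9, 3.4, 2.7, 3.1, 3.3)
  rt <- compare_groups(x, y)
  sp2 <- (4 * var(x) + 4 * var(y)) / 8
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(rt$test, "t")
  expect_equal(rt$statistic, t_hand, tolerance = 1e-12)

  expect_warning(rz <- compare_groups(rep(2, 4), rep(2, 3)), "zero variance")
  expect_equal(rz$p, 1)
  expect_error(compare_groups(1, 1:3), "at least 2")
})
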