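test_that("ANCOVA recovers an injected group effect on orthogonal covariates", {
  set.seed(1)
  n <- 80
  g <- rep(c("AF", "SA"), each = n / 2)
  x <- rnorm(n)
  x <- x - ave(x, g)             # orthogonalize covariate to the grouping
  y <- 2.5 * (g == "SA") + 0.7 * x + rnorm(n, 0, 1e-4)
  fit <- ancova(y, g, data.frame(x1 = x))
  expect_equal(unname(diff(fit$adjusted_means)), 2.5, tolerance = 1e-4)
  expect_lt(fit$table$p[fit$table$term == "region"], 1e-10)
})

test_that("single-covariate ANCOVA matches hand-computed normal equations", {
  # 6-unit table solved via the closed-form least squares fit
  y <- c(3.1, 4.0, 5.2, 6.3, 7.1, 8.4)
  g <- c("A", "A", "A", "B", "B", "B")
  x <- c(1, 2, 3, 1.5, 2.5, 3.5)
  X <- cbind(1, g == "B", x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  sse <- sum(res^2)
  # drop the group column for the type-II group SS
  X0 <- X[, -2]
  sse0 <- sum((y - X0 %*% solve(t(X0) %*% X0, t(X0) %*% y))^2)
  F_hand <- (sse0 - sse) / (sse / (6 - 3))
  fit <- ancova(y, g, data.frame(x = x))
  row <- fit$table[fit$table$term == "region", ]
  expect_equal(row$statistic, F_hand, tolerance = 1e-9)
  expect_equal(row$ss, sse0 - sse, tolerance = 1e-9)
  expect_equal(fit$error_ss, sse, tolerance = 1e-9)
  expect_equal(row$p, pf(F_hand, 1, 3, lower.tail = FALSE), tolerance = 1e-9)
})

test_that("ANCOVA rejects rank-deficient designs naming the column", {
  set.seed(2)
  x <- rnorm(30)
  expect_error(
    ancova(rnorm(30), rep(c("A", "B"), 15),
           data.frame(x1 = x, x2 = 2 * x)),
    "x2")
})

test_that("with no real covariate ANCOVA reduces to one-way ANOVA (F = t^2)", {
  set.seed(3)
  x <- rnorm(25, 10)
  y <- rnorm(25, 11)
  tt <- two_sample_t(x, y, variant = "pooled")
  av <- anova(lm(v ~ g, data = data.frame(v = c(x, y),
                                          g = rep(c("a", "b"), c(25, 25)))))
  expect_equal(av$`F value`[1], tt$statistic^2, tolerance = 1e-9)
  # the same identity through the ancova() interface without covariates
  fit <- ancova(c(x, y), rep(c("a", "b"), c(25, 25)))
  expect_equal(fit$table$statistic[fit$table$term == "region"],
               tt$statistic^2, tolerance = 1e-9)
})

test_that("type III ANCOVA is available and agrees on balanced designs", {
  set.seed(4)
  n <- 40
  g <- rep(c("A", "B"), each = n / 2)
  x <- rnorm(n)
  y <- 1 + (g == "B") + 0.5 * x + rnorm(n)
  f2 <- ancova(y, g, data.frame(x = x), ss_type = "II")
  f3 <- ancova(y, g, data.frame(x = x), ss_type = "III")
  r2 <- f2$table[f2$table$term == "region", ]
  r3 <- f3$table[f3$table$term == "region", ]
  expect_equal(r3$ss, r2$ss, tolerance = 1e-6)
  expect_equal(r3$p, r2$p, tolerance = 1e-6)
})

test_that("SAR with lambda fixed near zero reproduces OLS coefficients", {
  set.seed(5)
  n <- 60
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n)
  fit <- sar_error(y, data.frame(x = x), coords = coords, k = 5)
  ols <- coef(lm(y ~ x))
  # iid data: lambda near 0 and coefficients near OLS
  expect_lt(abs(fit$lambda), 0.35)
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 0.1)
  expect_equal(length(residuals(fit)), n)
  # degenerate weights are rejected
  W <- matrix(0, n, n)
  expect_error(sar_error(y, data.frame(x = x), W = W), "all-zero")
  expect_error(sar_error(y[1:10], data.frame(x = x[1:10]),
                         coords = coords[1:10, ]), "at least 20")
})

test_that("residual contrast is a Welch t test with location invariance", {
  set.seed(6)
  n <- 60
  coords <- cbind(runif(n), runif(n))
  x <- rnorm(n)
  g <- rep(c("AF", "SA"), each = n / 2)
  y <- 1 + x + rnorm(n)
  fit <- sar_error(y, data.frame(x = x), coords = coords, k = 5)
  ct <- residual_contrast(fit, g)
  ref <- t.test(fit$residuals[g == "AF"], fit$residuals[g == "SA"])
  expect_equal(ct$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(ct$p.value, ref$p.value, tolerance = 1e-9)
  # adding a constant to all residuals leaves t unchanged
  fit2 <- fit
  fit2$residuals <- fit$residuals + 100
  ct2 <- residual_contrast(fit2, g)
  expect_equal(ct2$statistic, ct$statistic, tolerance = 1e-9)
  expect_error(residual_contrast(fit, rep("AF", n)), "two groups")
})

test_that("identical residual distributions give t = 0, p = 1", {
  fit <- structure(list(residuals = rep(c(1, 2, 3), 2),
                        residuals_filtered = rep(c(1, 2, 3), 2)),
                   class = "sar_error")
  ct <- residual_contrast(fit, rep(c("A", "B"), 3))
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p.value, 1)
})

test_that("spearman_rho handles monotone maps, reversals and ties", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rho(x, x^2), 1)
  expect_equal(spearman_rho(x, -x), -1)
  # tied data against hand-averaged ranks
  x2 <- c(1, 2, 2, 3, 5, 5)
  y2 <- c(2, 1, 4, 4, 6, 7)
  rx <- rank(x2)
  ry <- rank(y2)
  expect_equal(spearman_rho(x2, y2), cor(rx, ry), tolerance = 1e-12)
  expect_error(spearman_rho(c(1, 1, 1), x[1:3]), "constant")
  expect_error(spearman_rho(1:2, 1:2), "length")
})

test_that("two-sample t matches the textbook computation", {
  x <- c(5.1, 4.9, 6.0, 5.5)
  y <- c(4.2, 4.8, 4.4, 4.0, 4.6)
  sp2 <- ((4 - 1) * var(x) + (5 - 1) * var(y)) / (4 + 5 - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 5))
  got <- two_sample_t(x, y, variant = "pooled")
  expect_equal(got$statistic, t_hand, tolerance = 1e-12)
  expect_equal(got$p.value, 2 * pt(-abs(t_hand), 7), tolerance = 1e-12)
  # identical samples
  same <- two_sample_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # zero-variance conventions
  expect_equal(two_sample_t(c(1, 1), c(1, 1))$p.value, 1)
  expect_equal(two_sample_t(c(1, 1), c(2, 2))$p.value, 0)
  # Welch equals pooled with equal n and equal variances
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  expect_equal(two_sample_t(a, b, "welch")$statistic,
               two_sample_t(a, b, "pooled")$statistic, tolerance = 1e-12)
})
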