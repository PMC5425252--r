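# Group-level statistics: ANOVA, t-tests, ANCOVA, mixed ANOVA, Bayes factor.

test_that("one-way ANOVA matches a hand-built sums-of-squares table", {
  # groups {1,2,3}, {2,3,4}, {6,7,8}: SSb = 42, SSw = 6
  v <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  r <- one_way_anova(v, g)
  expect_equal(r$statistic, 21)
  expect_equal(r$df1, 2); expect_equal(r$df2, 6)
  expect_equal(r$p, pf(21, 2, 6, lower.tail = FALSE))
  expect_equal(r$effect_size, 42 / 48)

  # identical means, positive variance: F ~ 0
  r0 <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$effect_size, 0)

  expect_error(one_way_anova(1:3, c("a", "a", "b")), "at least 2")
})

test_that("pooled t-test and Cohen's d match hand computation", {
  r <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1 / sqrt(2 / 3))
  expect_equal(r$df1, 4)
  expect_equal(r$effect_size, -1)   # pooled SD is exactly 1

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$effect_size, 0)

  expect_error(two_sample_t(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("with two groups the ANOVA F equals the squared t", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(10, 0.5)
    f <- one_way_anova(c(a, b), rep(c("a", "b"), c(8, 10)))
    t <- two_sample_t(a, b)
    expect_equal(f$statistic, t$statistic^2, tolerance = 1e-10)
    expect_equal(f$p, t$p, tolerance = 1e-10)
  }
})

test_that("ANCOVA group F reduces to plain ANOVA for irrelevant covariates", {
  set.seed(31)
  n <- 60
  g <- rep(c("a", "b", "c"), each = n / 3)
  y <- rnorm(n) + rep(c(0, 0.5, 1), each = n / 3)
  # orthogonalize a random covariate against both outcome and group
  x <- residuals(lm(rnorm(n) ~ factor(g) + y))
  r <- ancova_group_effect(y, g, list(x = x))
  plain <- one_way_anova(y, g)
  # with a fully irrelevant covariate the adjusted group SS is unchanged
  expect_equal(r$effect_size, plain$effect_size, tolerance = 1e-10)
  # and the F differs only through one lost residual df
  expect_equal(r$statistic, plain$statistic * (n - 4) / (n - 3),
               tolerance = 1e-10)
  expect_equal(r$df1, 2); expect_equal(r$df2, n - 4)
})

test_that("ANCOVA matches a normal-equations oracle on a 9-row design", {
  set.seed(33)
  g <- rep(c("a", "b", "c"), each = 3)
  x <- c(0.2, 1.1, -0.4, 0.9, -1.2, 0.3, 1.5, -0.8, 0.1)
  y <- c(1.0, 2.2, 0.4, 2.5, 0.1, 1.9, 4.8, 2.1, 3.4)
  r <- ancova_group_effect(y, g, list(x = x))

  # oracle: explicit least squares via solve() on both design matrices
  X_full <- cbind(1, g == "b", g == "c", x)
  X_red <- cbind(1, x)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  rss_f <- rss(X_full); rss_r <- rss(X_red)
  f_oracle <- ((rss_r - rss_f) / 2) / (rss_f / (9 - 4))
  expect_equal(r$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(r$effect_size, (rss_r - rss_f) / sum((y - mean(y))^2),
               tolerance = 1e-10)

  # collinear covariate named in the error
  expect_error(ancova_group_effect(y, g, list(x = x, x2 = 2 * x)),
               "collinear")
})

test_that("mixed ANOVA matches the aov error-strata oracle", {
  set.seed(44)
  n <- 12
  g <- rep(c("p1", "p2"), each = n / 2)
  cc <- rnorm(n, 0.8, 0.1)
  ee <- rnorm(n, 0.6, 0.1) + ifelse(g == "p1", 0.08, 0)
  r <- mixed_anova_confidence(cc, ee, g)

  long <- data.frame(y = c(cc, ee), subject = factor(rep(1:n, 2)),
                     g = factor(rep(g, 2)),
                     w = factor(rep(c("c", "e"), each = n)))
  fit <- aov(y ~ g * w + Error(subject), data = long)
  s <- summary(fit)
  f_between <- s[["Error: subject"]][[1]]
  f_within <- s[["Error: Within"]][[1]]
  expect_equal(r$statistic[1], f_between["g", "F value"], tolerance = 1e-8)
  expect_equal(r$statistic[2], f_within["w", "F value"], tolerance = 1e-8)
  expect_equal(r$statistic[3], f_within["g:w", "F value"], tolerance = 1e-8)
  expect_equal(r$p[3], f_within["g:w", "Pr(>F)"], tolerance = 1e-8)

  # effect sizes are proportions of total SS and the decomposition balances
  expect_true(all(r$effect_size >= 0 & r$effect_size <= 1))
})

test_that("a crossed-means pattern loads on the interaction", {
  g <- rep(c("p1", "p2"), each = 3)
  cc <- c(0.9, 0.9, 0.9, 0.5, 0.5, 0.5) + c(0, .01, -.01, 0, .01, -.01)
  ee <- c(0.5, 0.5, 0.5, 0.9, 0.9, 0.9) + c(.01, 0, -.01, .01, 0, -.01)
  r <- mixed_anova_confidence(cc, ee, g)
  expect_gt(r$statistic[3], 100 * max(r$statistic[1:2], na.rm = TRUE))
  expect_gt(r$effect_size[3], 0.9)

  # balanced cell means everywhere: every F vanishes
  cc0 <- c(.70, .72, .70, .72)
  ee0 <- cc0 + c(1e-3, -1e-3, 1e-3, -1e-3)
  r0 <- mixed_anova_confidence(cc0, ee0, rep(c("a", "b"), each = 2))
  expect_lt(r0$statistic[1], 1e-16)
  expect_lt(r0$statistic[2], 1e-16)
  expect_lt(r0$statistic[3], 1e-16)

  expect_error(mixed_anova_confidence(cc, ee, rep("a", 6)), "two groups")
})

test_that("JZS Bayes factor matches independent Simpson quadrature", {
  grid <- expand.grid(t = c(0, 0.74, 1.5, 2.5),
                      n1 = c(10, 20), n2 = c(10, 18),
                      r = c(sqrt(2) / 2, 1))
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], {
      bf_imp <- metacogsim:::jzs_bf10_t(t, n1, n2, r)
      bf_oracle <- simpson_bf10(t, n1, n2, r, n_grid = 8001)
      expect_equal(bf_imp, bf_oracle, tolerance = 5e-5)
    })
  }
})

test_that("Bayes factor behaves correctly at the anchors", {
  # no observed effect at n = 20/group: the null is favoured
  s <- samples_with_t(0, 20, 20)
  r <- bayes_factor_t(s$a, s$b)
  expect_equal(r$statistic, 0, tolerance = 1e-10)
  expect_gt(r$bf01, 3)

  # a vanishing prior scale collapses the alternative onto the null
  r_tiny <- bayes_factor_t(s$a, s$b + 0.1, r_scale = 1e-4)
  expect_equal(r_tiny$bf01, 1, tolerance = 1e-3)

  # normal unit-information variant is finite and sensible
  r_norm <- bayes_factor_t(s$a, s$b, prior = "normal")
  expect_gt(r_norm$bf01, 1)

  expect_error(bayes_factor_t(s$a, s$b, r_scale = 0), "r_scale")
})

test_that("a moderate observed t at n=20/18 and unit scale gives BF01 near 3.3", {
  # BF01 depends on the data only through (t, n1, n2); construct samples
  # with pooled t exactly 0.74 as reported for a null-ish group contrast
  s <- samples_with_t(0.74, 20, 18)
  r <- bayes_factor_t(s$a, s$b, r_scale = 1)
  expect_equal(r$statistic, 0.74, tolerance = 1e-10)
  expect_equal(r$bf01, 3.31, tolerance = 0.005)
})

test_that("type-I error of the pooled t-test is nominal under the null", {
  set.seed(55)
  reject <- vapply(1:400, function(i) {
    a <- rnorm(20); b <- rnorm(20)
    two_sample_t(a, b)$p < 0.05
  }, logical(1))
  # binomial 99.9% band around 0.05 at 400 draws
  expect_gt(mean(reject), 0.05 - 3.3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(mean(reject), 0.05 + 3.3 * sqrt(0.05 * 0.95 / 400))
})
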