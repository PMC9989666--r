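test_that("one-way ANOVA reproduces the textbook toy table", {
  df <- data.frame(value = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                   group = rep(c("a", "b", "c"), each = 3))
  res <- one_way_anova(df)
  expect_equal(res$statistic, 3, tolerance = 1e-12)
  expect_equal(c(res$df1, res$df2), c(2, 6))
  expect_equal(res$p_value, stats::pf(3, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)

  # equal group means: F ~ 0
  df0 <- data.frame(value = rep(c(1, 2, 3), 3), group = rep(c("a", "b", "c"), each = 3))
  expect_lt(one_way_anova(df0)$statistic, 1e-20)
  expect_error(one_way_anova(data.frame(value = 1:3, group = c("a", "a", "b"))),
               "2 subjects")
})

test_that("ANOVA F equals the squared two-sample t on two groups", {
  set.seed(61)
  df <- data.frame(value = stats::rnorm(20), group = rep(c("a", "b"), each = 10))
  f <- one_way_anova(df)$statistic
  t <- stats::t.test(value ~ group, data = df, var.equal = TRUE)$statistic
  expect_equal(f, unname(t)^2, tolerance = 1e-10)
})

test_that("permutation t-test has the stated behaviour", {
  set.seed(71)
  a <- stats::rnorm(15)
  # identical samples: p ~ 1, d = 0
  res <- permutation_ttest(a, a, n_perm = 500, seed = 1)
  expect_gt(res$p_value, 0.9)
  expect_equal(res$effect_size, 0, tolerance = 1e-12)
  # clearly separated samples: tiny p
  b <- stats::rnorm(20); c2 <- stats::rnorm(20) + 10
  res2 <- permutation_ttest(b, c2, n_perm = 10000, seed = 2)
  expect_lte(res2$p_value, 1e-3)
  # reproducible under a fixed seed; never exactly zero
  res3 <- permutation_ttest(b, c2, n_perm = 10000, seed = 2)
  expect_identical(res2$p_value, res3$p_value)
  expect_gt(res2$p_value, 0)
  expect_error(permutation_ttest(rep(1, 5), rep(1, 5)), "variance")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(81)
  reps <- 200
  hits <- 0L
  for (i in seq_len(reps)) {
    a <- stats::rnorm(10); b <- stats::rnorm(10)
    p <- permutation_ttest(a, b, n_perm = 2000, seed = i)$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  rate <- hits / reps
  expect_gte(rate, 0.03 - 1e-12)
  expect_lte(rate, 0.07 + 1e-12)
})

test_that("BH step-up adjustment is exact, monotone and order-invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  set.seed(91)
  p <- stats::runif(20)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in raw p
  perm <- sample(20)
  expect_equal(bh_fdr(p[perm]), adj[perm])
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("summary-statistic t-test reproduces the published cohort comparison", {
  # healthy controls (printed summary) vs the 21 patients with complete data
  demo <- load_demographics_fixture()
  pat <- demo$age[demo$scan != "Not available"]
  res <- summary_stats_ttest(35.75, 11.42, 20, mean(pat), stats::sd(pat), 21)
  expect_equal(res$df, 39)
  expect_equal(round(res$statistic, 2), -0.57)
  expect_equal(round(res$p_value, 3), 0.571)
  expect_equal(round(res$effect_size, 2), -0.18)   # Hedges' g

  z <- summary_stats_ttest(5, 1, 10, 5, 1, 10)
  expect_equal(z$statistic, 0)
  expect_equal(z$effect_size, 0)
  expect_error(summary_stats_ttest(1, 0, 10, 2, 1, 10), "SD")
})

test_that("Spearman correlation uses tie-corrected ranks and the t-approximation", {
  expect_equal(spearman_cor(1:5, (1:5)^3)$estimate, 1)
  expect_equal(spearman_cor(1:5, rev(1:5))$estimate, -1)
  x <- c(1, 2, 3, 4, 5); y <- c(3, 1, 4, 2, 5)
  rho <- spearman_cor(x, y)
  expect_equal(rho$estimate, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  tref <- rho$estimate * sqrt(3 / (1 - rho$estimate^2))
  expect_equal(rho$statistic, tref, tolerance = 1e-12)
  expect_equal(rho$p_value, 2 * stats::pt(-abs(tref), 3), tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 2:1), "3 complete")
})

test_that("ANCOVA adjusts the group effect for covariates", {
  set.seed(101)
  n <- 30
  g <- rep(c("a", "b", "c"), each = n / 3)
  shift <- c(a = 0, b = 1, c = 2)[g]
  cov_orth <- stats::rnorm(n)
  y <- shift + stats::rnorm(n, sd = 0.5)
  df <- data.frame(value = y, group = g, cov = cov_orth)
  plain <- one_way_anova(df)
  adj <- ancova(df, covariates = "cov")
  expect_lt(abs(adj$statistic - plain$statistic) / plain$statistic, 0.25)

  # outcome identical to covariate: the group increment in explained sum of
  # squares is numerically zero (the F ratio itself is 0/0-degenerate there,
  # so the increment is the stable quantity to pin down)
  df2 <- data.frame(value = cov_orth, group = g, cov = cov_orth)
  fit_r <- stats::lm(value ~ cov, data = df2)
  fit_f <- stats::lm(value ~ cov + group, data = df2)
  expect_lt(stats::deviance(fit_r) - stats::deviance(fit_f),
            1e-20 * stats::var(df2$value))
  expect_true(is.finite(ancova(df2, covariates = "cov")$statistic))

  # constant covariate: dropped, reduces to plain ANOVA
  df3 <- data.frame(value = y, group = g, cov = rep(2, n))
  expect_message(res3 <- ancova(df3, covariates = "cov"), "constant")
  expect_equal(res3$statistic, plain$statistic, tolerance = 1e-12)

  # collinear covariates: rank deficiency is named
  df4 <- data.frame(value = y, group = g, c1 = cov_orth, c2 = 2 * cov_orth)
  expect_error(ancova(df4, covariates = c("c1", "c2")), "c2")
})
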