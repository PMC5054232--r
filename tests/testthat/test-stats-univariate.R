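test_that("one-way ANOVA matches hand-computed sums of squares", {
  # SSb = 13.5, SSw = 4 -> F = 13.5 / (4/4) = 13.5
  res <- anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 13.5)
  expect_equal(res$df, c(1, 4))
  expect_equal(res$effect, 13.5 / 17.5)

  eq <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$effect, 0)

  expect_error(anova_oneway(rep(1, 6), rep(c("a", "b"), each = 3)),
               "zero within-group variance")
})

test_that("partial eta squared identity reproduces the published effect size", {
  # F = 5.52 on (1, 92) prints as eta_p^2 = .06
  expect_equal(eta_squared_from_f(5.52, 1, 92), 5.52 / 97.52)
  expect_equal(round(eta_squared_from_f(5.52, 1, 92), 2), 0.06)
  res <- anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$effect,
               eta_squared_from_f(res$statistic, res$df[1], res$df[2]))
})

test_that("Mann-Whitney U follows the min convention with effect size Z/sqrt(N)", {
  sep <- mann_whitney(c(1, 2, 3, 4), rep(c("a", "b"), each = 2))
  expect_equal(sep$statistic, 0)

  same <- mann_whitney(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 3 * 3 / 2)
  expect_equal(same$extra$Z, 0)

  # published arithmetic: U = 389.5 with n = (56, 40), no ties
  z <- (389.5 - 56 * 40 / 2) / sqrt(56 * 40 * 97 / 12)
  expect_equal(round(z, 2), -5.43)
  expect_equal(round(z / sqrt(96), 2), -0.55)
  expect_error(mann_whitney(c(1, 2), c("a", "a")), "two groups")
})

test_that("chi-square association reproduces the reconstructed reward table", {
  res <- chi_square_assoc(matrix(c(31, 11, 25, 29), nrow = 2))
  expect_equal(res$statistic, 7.357823, tolerance = 1e-6)
  expect_equal(res$effect, sqrt(7.357823 / 96), tolerance = 1e-6)
  expect_equal(res$df, 1)

  indep <- chi_square_assoc(matrix(10, 2, 2))
  expect_equal(indep$statistic, 0)
  expect_equal(indep$effect, 0)

  expect_error(chi_square_assoc(matrix(c(0, 0, 5, 5), 2)), "degenerate")
})

test_that("independent t test uses the pooled variance", {
  res <- t_test_independent(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)

  same <- t_test_independent(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # swapping labels flips the sign, not the p value
  flip <- t_test_independent(c(1, 2, 3, 4, 5, 6), rep(c("b", "a"), each = 3))
  expect_equal(flip$statistic, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(flip$p, res$p)
})

test_that("U, chi-square, t and F match brute-force oracles on random small data", {
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- sample(0:8, n1, replace = TRUE)  # ties likely
    y <- sample(0:8, n2, replace = TRUE)
    v <- c(x, y); g <- rep(c("a", "b"), c(n1, n2))

    expect_equal(mann_whitney(v, g)$statistic, oracle_u(x, y))
    ssw <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
    if (ssw > 0) {
      expect_equal(anova_oneway(v, g)$statistic, oracle_f(v, g),
                   tolerance = 1e-10)
      expect_equal(t_test_independent(v, g)$statistic, oracle_t(x, y),
                   tolerance = 1e-10)
    }

    counts <- matrix(sample(1:9, 6, replace = TRUE), nrow = 2)
    expect_equal(chi_square_assoc(counts)$statistic, oracle_chisq(counts),
                 tolerance = 1e-10)
  }
})

test_that("univariate tests agree with the standard reference routines", {
  set.seed(7)
  x <- rnorm(12); y <- rnorm(10, 0.5)
  v <- c(x, y); g <- rep(c("a", "b"), c(12, 10))

  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  mw <- mann_whitney(v, g)
  expect_equal(min(wt$statistic, 120 - wt$statistic), mw$statistic)
  expect_equal(wt$p.value, mw$p, tolerance = 1e-10)

  av <- anova(aov(v ~ g))
  expect_equal(anova_oneway(v, g)$statistic, av$`F value`[1],
               tolerance = 1e-10)
  expect_equal(anova_oneway(v, g)$p, av$`Pr(>F)`[1], tolerance = 1e-10)

  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(t_test_independent(v, g)$statistic,
               unname(tt$statistic), tolerance = 1e-10)
  expect_equal(t_test_independent(v, g)$p, tt$p.value, tolerance = 1e-10)

  counts <- matrix(c(12, 5, 9, 14), 2)
  ct <- chisq.test(counts, correct = FALSE)
  expect_equal(chi_square_assoc(counts)$statistic, unname(ct$statistic),
               tolerance = 1e-10)
})

test_that("age correlations pick Pearson or Spearman by measurement scale", {
  age <- c(4, 5, 6, 7, 8)
  res <- age_correlation(age, 2 * age, "pearson")
  expect_equal(res$statistic, 1)
  expect_equal(res$p, 0)

  # monotone nonlinear: rho = 1 but r < 1
  y <- age^2
  expect_equal(age_correlation(age, y, "spearman")$statistic, 1)
  expect_lt(age_correlation(age, y, "pearson")$statistic, 1)

  # agrees with cor.test's t approximation
  set.seed(5)
  a <- runif(30, 4, 8); b <- a + rnorm(30)
  ct <- cor.test(a, b)
  pr <- age_correlation(a, b, "pearson")
  expect_equal(pr$statistic, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(pr$p, ct$p.value, tolerance = 1e-10)
  cs <- suppressWarnings(cor.test(a, round(b), method = "spearman"))
  sp <- age_correlation(a, round(b), "spearman")
  expect_equal(sp$statistic, unname(cs$estimate), tolerance = 1e-10)

  expect_warning(age_correlation(c(1, 2, 3), c(1, 2, 4)), "unreliable")
})

test_that("the battery correlates all 14 variables with age using the declared scales", {
  p <- default_calibration(n_control = 40, n_adhd = 0, seed = 3)
  tab <- simulate_cohort(p)
  res <- correlate_with_age(tab)
  expect_equal(nrow(res), 14)
  expect_setequal(res$variable, outcome_variables()$variable)
  ord <- c("dressing_total", "sandwich_total", "rocket_choice",
           "balloon_correct")
  expect_true(all(res$method[res$variable %in% ord] == "spearman"))
  expect_true(all(res$method[!res$variable %in% ord] == "pearson"))
  expect_true(all(res$n <= 40))
})
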