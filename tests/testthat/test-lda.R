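sim_lda_data <- function(n1, n2, p, shift = 1, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * p), n1),
             matrix(rnorm(n2 * p, shift), n2))
  tab <- as.data.frame(X)
  names(tab) <- paste0("v", seq_len(p))
  tab$group <- rep(c("control", "adhd"), c(n1, n2))
  tab
}

test_that("discriminant analysis matches the reference implementation", {
  skip_if_not_installed("MASS")
  for (seed in 1:5) {
    p <- sample(2:5, 1)
    n1 <- sample(15:30, 1); n2 <- sample(15:30, 1)
    tab <- sim_lda_data(n1, n2, p, shift = 0.8, seed = seed)
    vars <- paste0("v", seq_len(p))
    mine <- lda_two_group(tab, variables = vars)
    ref <- MASS::lda(tab[, vars], grouping = tab$group,
                     prior = c(0.5, 0.5))
    pred <- predict(ref)$class

    # same resubstitution labels under equal priors
    mypred <- ifelse(
      abs(mine$scores - mean(mine$scores[tab$group == "adhd"])) <
        abs(mine$scores - mean(mine$scores[tab$group == "control"])),
      "adhd", "control")
    expect_equal(as.character(pred), unname(mypred))

    # coefficients proportional up to sign
    a <- mine$raw_coefficients
    b <- drop(ref$scaling)
    expect_equal(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1,
                 tolerance = 1e-8)

    # Wilks' lambda agrees with the MANOVA reference
    wl <- summary(manova(as.matrix(tab[, vars]) ~ tab$group),
                  test = "Wilks")$stats[1, 2]
    expect_equal(mine$wilks_lambda, unname(wl), tolerance = 1e-8)
  }
})

test_that("no group separation drives Wilks' lambda to 1 and chi-square to 0", {
  tab <- sim_lda_data(400, 400, 3, shift = 0, seed = 99)
  res <- lda_two_group(tab, variables = c("v1", "v2", "v3"))
  expect_gt(res$wilks_lambda, 0.98)
  expect_lt(res$chi2, qchisq(0.999, df = 3) + 5)
  expect_gt(res$p, 1e-4)
})

test_that("a single variable reduces to the one-way ANOVA decomposition", {
  tab <- sim_lda_data(20, 25, 1, shift = 1.2, seed = 3)
  res <- lda_two_group(tab, variables = "v1")
  av <- anova_oneway(tab$v1, tab$group)
  # lambda = SSwithin / SStotal = 1 / (1 + F * df1/df2)
  expect_equal(res$wilks_lambda,
               1 / (1 + av$statistic * av$df[1] / av$df[2]),
               tolerance = 1e-10)
  # Bartlett transform at p = 1, g = 2
  expect_equal(res$chi2, -(45 - 1 - 3 / 2) * log(res$wilks_lambda),
               tolerance = 1e-10)
})

test_that("the discriminant is invariant to affine rescaling of a column", {
  tab <- sim_lda_data(25, 25, 4, shift = 0.9, seed = 11)
  vars <- paste0("v", 1:4)
  r1 <- lda_two_group(tab, variables = vars)
  tab2 <- tab
  tab2$v2 <- tab2$v2 * 10 + 5
  r2 <- lda_two_group(tab2, variables = vars)
  expect_equal(r1$wilks_lambda, r2$wilks_lambda, tolerance = 1e-10)
  expect_equal(r1$overall, r2$overall)
  expect_equal(unname(r1$confusion), unname(r2$confusion))
  # structure matrix is scale-free too
  expect_equal(r1$structure_matrix, r2$structure_matrix, tolerance = 1e-8)
})

test_that("structure matrix entries are pooled within-group correlations in [-1, 1]", {
  tab <- sim_lda_data(30, 30, 3, shift = 1, seed = 21)
  res <- lda_two_group(tab, variables = c("v1", "v2", "v3"))
  expect_true(all(abs(res$structure_matrix) <= 1 + 1e-12))
  expect_true(res$wilks_lambda > 0 && res$wilks_lambda <= 1)
})

test_that("collinear columns are named in the singularity error", {
  tab <- sim_lda_data(20, 20, 2, shift = 1, seed = 5)
  tab$v3 <- tab$v1 + tab$v2
  expect_error(lda_two_group(tab, variables = c("v1", "v2", "v3")),
               "collinear")
})

test_that("classification metrics reproduce the published arithmetic", {
  m <- classification_metrics(c(controls_correct = 41, controls_total = 57,
                                adhd_correct = 35, adhd_total = 40))
  expect_equal(m$overall, 76 / 97)
  expect_equal(round(m$overall, 2), 0.78)
  expect_equal(m$sensitivity, 35 / 40)       # 0.875, prints as 88%
  expect_equal(m$specificity, 41 / 57)

  perfect <- matrix(c(10, 0, 0, 10), 2,
                    dimnames = list(c("control", "adhd"),
                                    c("control", "adhd")))
  mp <- classification_metrics(perfect)
  expect_equal(mp$sensitivity, 1)
  expect_equal(mp$specificity, 1)
  expect_equal(mp$overall, 1)

  expect_error(classification_metrics(c(1, 0, 1, 2)), "positive")
})

test_that("stronger group separation never hurts resubstitution accuracy", {
  accs <- sapply(c(0.2, 0.6, 1.0, 1.6, 2.4), function(shift) {
    tab <- sim_lda_data(150, 150, 3, shift = shift, seed = 77)
    lda_two_group(tab, variables = c("v1", "v2", "v3"))$overall
  })
  expect_true(all(diff(accs) >= -0.01))
  expect_gt(accs[5], accs[1])
})
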