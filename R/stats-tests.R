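#' Generic univariate test result
#'
#' A light container used by every univariate test in the battery: the
#' statistic's name and value, its degrees of freedom (one or two
#' components), the two-tailed p value, the matching effect size (partial
#' eta squared for F, Cramer's V for chi-square, r = Z/sqrt(N) for
#' Mann-Whitney), and the number of observations actually used after
#' listwise deletion.
#'
#' @param test statistic name ("r", "rho", "t", "F", "U", "chisq").
#' @param statistic statistic value.
#' @param df numeric vector of 1 or 2 degrees of freedom (may be NA).
#' @param p two-tailed p value.
#' @param effect effect-size value (NA if not applicable).
#' @param effect_name effect-size label.
#' @param n number of observations used.
#' @param extra optional named list of auxiliary values (e.g. Z for U).
#' @return An object of class `test_result`.
#' @export
test_result <- function(test, statistic, df = NA_real_, p = NA_real_,
                        effect = NA_real_, effect_name = NA_character_,
                        n = NA_integer_, extra = list()) {
  structure(list(test = test, statistic = as.numeric(statistic),
                 df = as.numeric(df), p = as.numeric(p),
                 effect = as.numeric(effect),
                 effect_name = as.character(effect_name),
                 n = as.integer(n), extra = extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- if (all(is.na(x$df))) "" else
    paste0("(", paste(format(x$df, digits = 4), collapse = ", "), ")")
  cat(sprintf("%s%s = %.4g, p = %.4g", x$test, dfs, x$statistic, x$p))
  if (!is.na(x$effect))
    cat(sprintf(", %s = %.3g", x$effect_name, x$effect))
  cat(sprintf(" [n = %d]\n", x$n))
  invisible(x)
}

two_group_split <- function(values, groups) {
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  lev <- sort(unique(groups))
  if (length(lev) != 2)
    stop("exactly two groups required, got ", length(lev))
  # control first when present, for stable statistic signs
  if ("control" %in% lev) lev <- c("control", setdiff(lev, "control"))
  list(x = values[groups == lev[1]], y = values[groups == lev[2]],
       levels = lev)
}

#' One-way ANOVA between-groups test with partial eta squared
#'
#' The general-linear-model univariate group comparison: F with
#' `(k - 1, N - k)` degrees of freedom from the between/within sums of
#' squares, and partial eta squared
#' `SS_between / (SS_between + SS_within)`.
#'
#' @param values numeric outcome.
#' @param groups group labels (2 or more levels; the battery uses 2).
#' @return A [test_result()] with test `"F"` and effect `"eta_p2"`.
#' @examples
#' anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  lev <- unique(groups)
  if (length(lev) < 2) stop("at least two groups required")
  sizes <- table(groups)
  if (any(sizes < 2)) stop("each group needs at least 2 observations")
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(sizes[names(means)] * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- length(lev) - 1
  df2 <- length(values) - length(lev)
  if (ssw <= 0) stop("zero within-group variance")
  f <- (ssb / df1) / (ssw / df2)
  test_result("F", f, df = c(df1, df2),
              p = stats::pf(f, df1, df2, lower.tail = FALSE),
              effect = ssb / (ssb + ssw), effect_name = "eta_p2",
              n = length(values))
}

#' Partial eta squared from an F statistic
#'
#' The identity `eta_p^2 = F * df1 / (F * df1 + df2)`.
#'
#' @param f F value.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return Partial eta squared.
#' @export
eta_squared_from_f <- function(f, df1, df2) {
  f * df1 / (f * df1 + df2)
}

#' Mann-Whitney U test with normal approximation and effect size r
#'
#' Reports the smaller of the two U statistics, the tie-corrected normal
#' approximation Z, its two-tailed p, and the effect size `r = Z / sqrt(N)`
#' (negative under the reporting convention, since the smaller U lies below
#' its null mean).
#'
#' @param values numeric outcome.
#' @param groups two-level group labels.
#' @return A [test_result()] with test `"U"`, effect `"r"`, and `Z` in
#'   `extra`.
#' @export
mann_whitney <- function(values, groups) {
  gs <- two_group_split(values, groups)
  n1 <- length(gs$x); n2 <- length(gs$y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  pooled <- c(gs$x, gs$y)
  n <- n1 + n2
  rk <- rank(pooled)  # average ranks for ties
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  mu <- n1 * n2 / 2
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0
  p <- 2 * stats::pnorm(-abs(z))
  test_result("U", u, df = NA_real_, p = min(p, 1),
              effect = z / sqrt(n), effect_name = "r",
              n = n, extra = list(Z = z, U1 = u1, U2 = u2))
}

#' Pearson chi-square test of association with Cramer's V
#'
#' Pearson chi-square on a contingency table, without continuity
#' correction, with `df = (r - 1)(c - 1)` and
#' `V = sqrt(chisq / (N * min(r - 1, c - 1)))`.
#'
#' @param counts contingency table (matrix of non-negative counts).
#' @return A [test_result()] with test `"chisq"` and effect `"V"`.
#' @examples
#' chi_square_assoc(matrix(c(31, 11, 25, 29), nrow = 2))
#' @export
chi_square_assoc <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: a row or column margin is zero")
  n <- sum(counts)
  expected <- outer(rs, cs) / n
  chisq <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  if (df < 1) stop("table must have at least 2 rows and 2 columns")
  v <- sqrt(chisq / (n * min(nrow(counts) - 1, ncol(counts) - 1)))
  test_result("chisq", chisq, df = df,
              p = stats::pchisq(chisq, df, lower.tail = FALSE),
              effect = v, effect_name = "V", n = n)
}

#' Independent-samples t test (pooled variance)
#'
#' Student's t with pooled variance, `df = n1 + n2 - 2`, two-tailed p.
#' Used in the battery to check group equivalence on the verbal-IQ
#' covariate before the main analyses.
#'
#' @param values numeric outcome.
#' @param groups two-level group labels.
#' @return A [test_result()] with test `"t"`.
#' @export
t_test_independent <- function(values, groups) {
  gs <- two_group_split(values, groups)
  n1 <- length(gs$x); n2 <- length(gs$y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  sp2 <- ((n1 - 1) * stats::var(gs$x) + (n2 - 1) * stats::var(gs$y)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  tval <- (mean(gs$x) - mean(gs$y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  test_result("t", tval, df = df,
              p = 2 * stats::pt(-abs(tval), df),
              n = n1 + n2)
}

#' Correlation of one variable with age
#'
#' Pearson correlation for scale variables; Spearman rank correlation
#' (average ranks for ties) for ordinal variables. The two-tailed p value
#' uses the t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom for both methods.
#'
#' @param age numeric age in years.
#' @param y numeric outcome.
#' @param method `"pearson"` or `"spearman"`.
#' @return A [test_result()] with test `"r"` or `"rho"`; `reliable = FALSE`
#'   in `extra` (with a warning) when fewer than 4 complete pairs remain.
#' @export
age_correlation <- function(age, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- !is.na(age) & !is.na(y)
  age <- age[keep]; y <- y[keep]
  n <- length(age)
  reliable <- n >= 4
  if (!reliable)
    warning("fewer than 4 complete pairs; correlation flagged unreliable")
  if (n < 3 || stats::sd(age) == 0 || stats::sd(y) == 0)
    return(test_result(if (method == "pearson") "r" else "rho",
                       NA_real_, df = NA_real_, p = NA_real_, n = n,
                       extra = list(reliable = FALSE)))
  if (method == "spearman") {
    age <- rank(age); y <- rank(y)
  }
  r <- stats::cov(age, y) / (stats::sd(age) * stats::sd(y))
  r <- max(-1, min(1, r))
  df <- n - 2
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  }
  test_result(if (method == "pearson") "r" else "rho", r,
              df = df, p = p, n = n, extra = list(reliable = reliable))
}

#' Age-correlation battery over the analysis variables
#'
#' Runs [age_correlation()] for each of the 14 analysis variables, choosing
#' Pearson or Spearman from the variable's measurement scale (see
#' [outcome_variables()]), with pairwise-complete observations.
#'
#' @param table outcome data frame with an `age` column (typically the
#'   normally developing children only).
#' @param variables variables to correlate; default all 14 analysis
#'   variables present in `table`.
#' @return Data frame with one row per variable: `variable`, `method`,
#'   `estimate`, `df`, `p`, `n`.
#' @export
correlate_with_age <- function(table, variables = NULL) {
  if (!"age" %in% names(table)) stop("table must contain an 'age' column")
  meta <- outcome_variables()
  if (is.null(variables))
    variables <- intersect(meta$variable, names(table))
  rows <- lapply(variables, function(v) {
    method <- if (meta$scale[match(v, meta$variable)] == "ordinal")
      "spearman" else "pearson"
    res <- age_correlation(table$age, table[[v]], method)
    data.frame(variable = v, method = method,
               estimate = res$statistic, df = res$df[1], p = res$p,
               n = res$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
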