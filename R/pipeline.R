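#' Run the full validation analysis chain
#'
#' The complete statistics chain applied to one cohort outcome table, in
#' order: (1) within-group outlier winsorization; (2) the age-correlation
#' battery over the normally developing children (their full age range);
#' (3) age matching — normally developing children younger than the cutoff
#' are excluded from all group comparisons; (4) group equivalence check on
#' verbal IQ (independent-samples t); (5) two-group discriminant analysis
#' of the 14 variables with resubstitution classification; (6) univariate
#' group tests per variable — chi-square association for the categorical
#' variables, and for continuous variables the general-linear-model F
#' unless the Brown-Forsythe check flags heterogeneous variances, in which
#' case the Mann-Whitney U is used.
#'
#' @param table outcome data frame (see [compile_outcomes()] /
#'   [simulate_cohort()]).
#' @param age_cutoff years; controls younger than this are excluded from
#'   group analyses (default 6, matching the clinical group's age range).
#' @param winsorize logical; apply [winsorize_outliers()] first.
#' @param priors classification priors for [lda_two_group()].
#' @param homogeneity_alpha significance level of the Brown-Forsythe check
#'   that routes a continuous variable to the Mann-Whitney test.
#' @return An object of class `battery_report`: list with
#'   `age_correlations` (data frame), `vocabulary` ([test_result()] or
#'   NULL), `discriminant` ([lda_two_group()] result), `group_tests`
#'   (data frame summary), `group_test_objects` (named list of
#'   [test_result()]), `winsorize_log`, `n_control_matched`, `n_adhd`.
#' @export
run_full_analysis <- function(table, age_cutoff = 6, winsorize = TRUE,
                              priors = c("equal", "proportional"),
                              homogeneity_alpha = 0.05) {
  priors <- match.arg(priors)
  needed <- c("group", "age", outcome_variables()$variable)
  miss <- setdiff(needed, names(table))
  if (length(miss))
    stop("table is missing columns: ", paste(miss, collapse = ", "))
  wlog <- NULL
  if (winsorize) {
    table <- winsorize_outliers(table)
    wlog <- attr(table, "winsorize_log")
  }
  controls <- table[table$group == "control" & !is.na(table$group), ]
  if (nrow(controls) == 0) stop("no control children in the table")
  age_cor <- correlate_with_age(controls)

  matched <- table[is.na(table$group) == FALSE &
                     (table$group != "control" | table$age >= age_cutoff), ]
  n_ctl <- sum(matched$group == "control")
  n_adhd <- sum(matched$group == "adhd")
  if (n_ctl < 2 || n_adhd < 2)
    stop("age matching left fewer than 2 children in a group")

  vocab <- NULL
  if ("vocabulary_iq" %in% names(matched) &&
      sum(!is.na(matched$vocabulary_iq)) >= 4)
    vocab <- t_test_independent(matched$vocabulary_iq, matched$group)

  disc <- lda_two_group(matched, priors = priors)

  meta <- outcome_variables()
  test_objects <- list()
  rows <- list()
  for (i in seq_len(nrow(meta))) {
    v <- meta$variable[i]
    x <- matched[[v]]
    g <- matched$group
    if (meta$categorical[i]) {
      res <- chi_square_assoc(table(x, g))
      chosen <- "chisq"
    } else {
      hom_p <- tryCatch(brown_forsythe(x, g)$p, error = function(e) 1)
      if (!is.na(hom_p) && hom_p < homogeneity_alpha) {
        res <- mann_whitney(x, g)
        chosen <- "U"
      } else {
        res <- anova_oneway(x, g)
        chosen <- "F"
      }
    }
    test_objects[[v]] <- res
    rows[[i]] <- data.frame(
      variable = v, test = chosen, statistic = res$statistic,
      df1 = res$df[1], df2 = if (length(res$df) > 1) res$df[2] else NA_real_,
      p = res$p, effect_name = res$effect_name, effect = res$effect,
      n = res$n, stringsAsFactors = FALSE)
  }

  structure(list(
    age_correlations = age_cor,
    vocabulary = vocab,
    discriminant = disc,
    group_tests = do.call(rbind, rows),
    group_test_objects = test_objects,
    winsorize_log = wlog,
    n_control_matched = n_ctl,
    n_adhd = n_adhd,
    age_cutoff = age_cutoff
  ), class = "battery_report")
}

#' Brown-Forsythe test of variance homogeneity
#'
#' One-way ANOVA on the absolute deviations from the group medians; used
#' to decide whether a continuous variable's group comparison can rely on
#' the homogeneity-of-variance assumption.
#'
#' @param values numeric outcome.
#' @param groups group labels.
#' @return A [test_result()] with test `"F"`.
#' @export
brown_forsythe <- function(values, groups) {
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  med <- tapply(values, groups, stats::median)
  anova_oneway(abs(values - med[groups]), groups)
}

#' @export
print.battery_report <- function(x, ...) {
  cat("<battery_report>\n")
  cat(sprintf("  groups after age matching (>= %g y): %d controls, %d ADHD\n",
              x$age_cutoff, x$n_control_matched, x$n_adhd))
  if (!is.null(x$winsorize_log) && nrow(x$winsorize_log))
    cat(sprintf("  winsorized values: %d (across %d group x variable cells)\n",
                sum(x$winsorize_log$n_replaced), nrow(x$winsorize_log)))
  sig <- x$age_correlations[!is.na(x$age_correlations$p) &
                              x$age_correlations$p < 0.05, ]
  cat(sprintf("  age correlations (controls): %d of %d significant at .05\n",
              nrow(sig), nrow(x$age_correlations)))
  if (!is.null(x$vocabulary))
    cat(sprintf("  vocabulary IQ equivalence: t(%g) = %.2f, p = %.3f\n",
                x$vocabulary$df, x$vocabulary$statistic, x$vocabulary$p))
  cat(sprintf("  discriminant: Wilks lambda = %.3f, chi2(%d) = %.1f, p = %.3g\n",
              x$discriminant$wilks_lambda, x$discriminant$df,
              x$discriminant$chi2, x$discriminant$p))
  cat(sprintf("  classification: sens %.2f, spec %.2f, overall %.2f\n",
              x$discriminant$sensitivity, x$discriminant$specificity,
              x$discriminant$overall))
  sig_g <- x$group_tests[x$group_tests$p < 0.05, "variable"]
  cat("  group differences at .05: ",
      if (length(sig_g)) paste(sig_g, collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}
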