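#' Two-group linear discriminant analysis
#'
#' Fisher's linear discriminant for two groups on the 14 analysis
#' variables: the discriminant direction is the pooled within-group
#' covariance inverse applied to the mean difference, scaled so the pooled
#' within-group variance of the discriminant scores is 1. Reports Wilks'
#' lambda (`det(W)/det(T)`, equivalently `1/(1 + lambda_1)` for the single
#' nonzero eigenvalue), Bartlett's chi-square approximation
#' `-(N - 1 - (p + g)/2) * ln(Lambda)` on `p (g - 1)` degrees of freedom,
#' standardized coefficients (raw coefficients times pooled within-group
#' SDs), the structure matrix (pooled within-group correlation of each
#' variable with the discriminant scores), and resubstitution
#' classification with the ADHD group as the positive class.
#'
#' @param table outcome data frame with a `group` column holding
#'   `"control"`/`"adhd"`; rows with any missing analysis variable are
#'   dropped (listwise deletion) and the n actually used is reported.
#' @param variables discriminating variables; default all 14 analysis
#'   variables present in `table`.
#' @param priors `"equal"` (default) or `"proportional"` prior
#'   probabilities for classification.
#' @return An object of class `discriminant_result` with elements
#'   `wilks_lambda`, `chi2`, `df`, `p`, `coefficients` (standardized),
#'   `raw_coefficients`, `structure_matrix`, `confusion` (2x2, rows =
#'   true group), `sensitivity`, `specificity`, `overall`, `n`, `n_dropped`,
#'   `group_means`, `scores`.
#' @export
lda_two_group <- function(table, variables = NULL,
                          priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  if (!"group" %in% names(table)) stop("table must contain a 'group' column")
  if (is.null(variables))
    variables <- intersect(outcome_variables()$variable, names(table))
  p <- length(variables)
  if (p < 1) stop("no discriminating variables found")
  keep <- !is.na(table$group) &
    stats::complete.cases(table[, variables, drop = FALSE])
  n_dropped <- sum(!keep)
  dat <- table[keep, , drop = FALSE]
  grp <- as.character(dat$group)
  lev <- unique(grp)
  if (length(lev) != 2) stop("exactly two groups required")
  if (all(c("control", "adhd") %in% lev)) lev <- c("control", "adhd")
  X <- as.matrix(dat[, variables, drop = FALSE])
  storage.mode(X) <- "double"
  n1 <- sum(grp == lev[1]); n2 <- sum(grp == lev[2])
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 complete rows")
  N <- n1 + n2
  m1 <- colMeans(X[grp == lev[1], , drop = FALSE])
  m2 <- colMeans(X[grp == lev[2], , drop = FALSE])
  Xc <- X
  Xc[grp == lev[1], ] <- sweep(X[grp == lev[1], , drop = FALSE], 2, m1)
  Xc[grp == lev[2], ] <- sweep(X[grp == lev[2], , drop = FALSE], 2, m2)
  W <- crossprod(Xc)                      # within-group SSCP
  Sw <- W / (N - 2)                       # pooled within-group covariance
  qrW <- qr(Sw)
  if (qrW$rank < p) {
    bad <- variables[qrW$pivot[seq.int(qrW$rank + 1L, p)]]
    stop("pooled within-group covariance is singular; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  a <- solve(Sw, m2 - m1)                 # raw discriminant direction
  a <- a / sqrt(drop(crossprod(a, Sw %*% a)))  # unit pooled within variance
  scores <- drop(X %*% a)
  s1 <- mean(scores[grp == lev[1]]); s2 <- mean(scores[grp == lev[2]])
  # Wilks' lambda via the single nonzero eigenvalue of W^-1 B
  ssb <- n1 * (s1 - mean(scores))^2 + n2 * (s2 - mean(scores))^2
  ssw <- sum((scores[grp == lev[1]] - s1)^2) +
    sum((scores[grp == lev[2]] - s2)^2)
  lambda1 <- ssb / ssw
  wilks <- 1 / (1 + lambda1)
  chi2 <- -(N - 1 - (p + 2) / 2) * log(wilks)
  df <- p
  pval <- stats::pchisq(chi2, df, lower.tail = FALSE)
  # standardized coefficients and structure matrix
  within_sd <- sqrt(diag(Sw))
  std_coef <- a * within_sd
  pooled_cov_xs <- drop(crossprod(Xc, scores - ave(scores, grp))) / (N - 2)
  structure_mat <- pooled_cov_xs / within_sd  # pooled SD of scores is 1
  names(std_coef) <- names(structure_mat) <- variables
  # resubstitution classification in discriminant space
  log_prior <- if (priors == "equal") c(0, 0) else log(c(n1, n2) / N)
  d1 <- (scores - s1)^2 / 2 - log_prior[1]
  d2 <- (scores - s2)^2 / 2 - log_prior[2]
  predicted <- ifelse(d2 < d1, lev[2], lev[1])
  confusion <- table(factor(grp, levels = lev),
                     factor(predicted, levels = lev))
  metrics <- classification_metrics(confusion,
                                    positive = if ("adhd" %in% lev) "adhd"
                                               else lev[2])
  structure(list(
    wilks_lambda = wilks, chi2 = chi2, df = df, p = pval,
    coefficients = std_coef, raw_coefficients = stats::setNames(a, variables),
    structure_matrix = structure_mat,
    confusion = confusion,
    sensitivity = metrics$sensitivity, specificity = metrics$specificity,
    overall = metrics$overall,
    n = N, n_dropped = n_dropped, levels = lev,
    group_means = rbind(stats::setNames(m1, variables),
                        stats::setNames(m2, variables)),
    scores = scores, priors = priors
  ), class = "discriminant_result")
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat("<discriminant_result> two-group linear discriminant analysis\n")
  cat(sprintf("  Wilks lambda = %.3f, chi2(%d) = %.2f, p = %.3g [n = %d]\n",
              x$wilks_lambda, x$df, x$chi2, x$p, x$n))
  cat(sprintf("  resubstitution: sensitivity %.3f, specificity %.3f, overall %.3f\n",
              x$sensitivity, x$specificity, x$overall))
  cat("  structure matrix (|r| sorted):\n")
  sm <- sort(abs(x$structure_matrix), decreasing = TRUE)
  for (v in names(sm))
    cat(sprintf("    %-24s % .2f\n", v, x$structure_matrix[v]))
  invisible(x)
}

#' Classification accuracy metrics from a confusion matrix
#'
#' Sensitivity is the fraction of true positive-class (ADHD) cases
#' correctly classified, specificity the fraction of true controls
#' correctly classified, and overall the pooled fraction correct.
#'
#' @param confusion 2x2 table/matrix with true groups in rows and predicted
#'   groups in columns (matching dimnames), or a named numeric vector
#'   `c(controls_correct, controls_total, adhd_correct, adhd_total)`.
#' @param positive name of the positive-class row (default `"adhd"`).
#' @return List with `sensitivity`, `specificity`, `overall`.
#' @examples
#' classification_metrics(c(controls_correct = 41, controls_total = 57,
#'                          adhd_correct = 35, adhd_total = 40))
#' @export
classification_metrics <- function(confusion, positive = "adhd") {
  if (is.matrix(confusion) || is.table(confusion)) {
    m <- as.matrix(confusion)
    if (nrow(m) != 2 || ncol(m) != 2) stop("confusion must be 2x2")
    rows <- rownames(m)
    if (is.null(rows) || !positive %in% rows)
      stop("confusion rows must name the true groups incl. '", positive, "'")
    neg <- setdiff(rows, positive)
    pos_correct <- m[positive, positive]; pos_total <- sum(m[positive, ])
    neg_correct <- m[neg, neg]; neg_total <- sum(m[neg, ])
  } else {
    v <- confusion
    stopifnot(length(v) == 4)
    neg_correct <- v[[1]]; neg_total <- v[[2]]
    pos_correct <- v[[3]]; pos_total <- v[[4]]
  }
  if (pos_total <= 0 || neg_total <= 0)
    stop("group totals must be positive")
  if (pos_correct > pos_total || neg_correct > neg_total)
    stop("correct counts cannot exceed group totals")
  list(sensitivity = pos_correct / pos_total,
       specificity = neg_correct / neg_total,
       overall = (pos_correct + neg_correct) / (pos_total + neg_total))
}
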