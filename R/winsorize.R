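#' Within-group outlier replacement
#'
#' For each group and each analysis variable, values whose z score within
#' that group exceeds the threshold (|z| > 3.29 by default) are replaced by
#' the group mean plus `sign(deviation) * 3` standard deviations: a high
#' outlier becomes `mean + 3 SD`, a low outlier `mean - 3 SD`, so extreme
#' scores are pulled to the edge of the plausible range instead of being
#' dropped. Group means and SDs are those of the original column (not
#' recomputed between replacements), so the operation is idempotent.
#'
#' @param table outcome data frame with a `group` column.
#' @param variables columns to treat; default all 14 analysis variables
#'   present in `table`.
#' @param z_threshold absolute z score beyond which a value is an outlier.
#' @param k replacement distance in SDs from the group mean.
#' @param recompute if TRUE (default) group moments are computed from the
#'   input table; if FALSE and the table carries the moments of a previous
#'   call (attribute `"winsorize_moments"`), those are reused, which makes
#'   repeated application idempotent.
#' @return The table with outliers replaced; the replacement log (one row
#'   per group x variable with at least one replacement) is attached as
#'   attribute `"winsorize_log"`, and the group moments used as
#'   `"winsorize_moments"`.
#' @examples
#' tab <- data.frame(group = rep("control", 30),
#'                   age = 6, magicland_clicks = c(rep(0, 29), 100))
#' w <- winsorize_outliers(tab)
#' attr(w, "winsorize_log")
#' @export
winsorize_outliers <- function(table, variables = NULL,
                               z_threshold = 3.29, k = 3,
                               recompute = TRUE) {
  if (!"group" %in% names(table)) stop("table must contain a 'group' column")
  if (is.null(variables))
    variables <- intersect(outcome_variables()$variable, names(table))
  prev <- attr(table, "winsorize_moments")
  reuse <- !recompute && !is.null(prev)
  moments <- if (reuse) prev else list()
  log_rows <- list()
  for (g in unique(stats::na.omit(table$group))) {
    idx <- which(table$group == g)
    for (v in variables) {
      x <- table[[v]][idx]
      key <- paste(g, v, sep = ".")
      if (reuse && !is.null(moments[[key]])) {
        m <- moments[[key]][1]
        s <- moments[[key]][2]
      } else {
        m <- mean(x, na.rm = TRUE)
        s <- stats::sd(x, na.rm = TRUE)
        moments[[key]] <- c(m, s)
      }
      if (is.na(s) || s == 0) {
        warning("zero or undefined SD for '", v, "' in group '", g,
                "'; skipped")
        next
      }
      z <- (x - m) / s
      out <- which(!is.na(z) & abs(z) > z_threshold)
      if (length(out)) {
        table[[v]][idx[out]] <- m + sign(x[out] - m) * k * s
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(group = g, variable = v, n_replaced = length(out),
                     stringsAsFactors = FALSE)
      }
    }
  }
  attr(table, "winsorize_log") <- if (length(log_rows))
    do.call(rbind, log_rows)
  else
    data.frame(group = character(0), variable = character(0),
               n_replaced = integer(0))
  attr(table, "winsorize_moments") <- moments
  table
}
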