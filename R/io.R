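#' @title Formats and end-to-end pipeline
#' @description
#' Event logs travel as JSON-lines: each log starts with a header line
#' `{"game": ..., "child": ..., "config_hash": ..., "meta": {...}}`
#' followed by one event per line `{"t": ..., "kind": ..., "target": ...}`;
#' several logs may be concatenated in one file. Cohort outcome tables
#' travel as comma-separated UTF-8 CSV with "." decimal separator, a
#' mandatory header, demographics first and the 14 analysis variables in
#' the fixed analysis order; missing values are empty fields.
#' @name battery-io
NULL

# Polynomial rolling hash over the serialized configuration; cheap content
# fingerprint so mixed-configuration log files can be detected.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(as_config_list(cfg)), auto_unbox = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write event logs to a JSON-lines file
#'
#' @param logs a single [event_log()] or a list of them.
#' @param path output file.
#' @param cfg the [game_config()] used, fingerprinted into each header.
#' @return Invisibly, the path.
#' @export
write_event_logs <- function(logs, path, cfg = game_config()) {
  if (inherits(logs, "event_log")) logs <- list(logs)
  ch <- config_hash(cfg)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (log in logs) {
    stopifnot(inherits(log, "event_log"))
    header <- list(game = log$game_id, child = log$child_id,
                   config_hash = ch)
    if (length(log$meta)) header$meta <- serialize_meta(log$meta)
    writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
    ev <- log$events
    for (i in seq_len(nrow(ev))) {
      writeLines(jsonlite::toJSON(list(t = ev$t[i], kind = ev$kind[i],
                                       target = ev$target[i]),
                                  auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

serialize_meta <- function(meta) {
  lapply(meta, function(m) {
    if (is.data.frame(m)) c(list(.df = TRUE), as.list(m)) else m
  })
}

deserialize_meta <- function(meta) {
  lapply(meta, function(m) {
    if (is.list(m) && isTRUE(m$.df)) {
      m$.df <- NULL
      as.data.frame(lapply(m, unlist), stringsAsFactors = FALSE)
    } else if (is.list(m) && length(m) && all(vapply(m, is.list, logical(1)))) {
      lapply(m, function(x) unlist(x))
    } else if (is.list(m)) {
      unlist(m)
    } else m
  })
}

#' Read event logs from a JSON-lines file
#'
#' Validates every log (known game ids, non-decreasing timestamps, event
#' kinds); malformed lines are reported with their line number.
#'
#' @param path a JSONL file written by [write_event_logs()].
#' @return List of [event_log()] objects (empty, with a warning, for an
#'   empty file).
#' @export
read_event_logs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty event-log file: ", path)
    return(list())
  }
  logs <- list()
  current <- NULL
  flush_current <- function(cur) {
    tryCatch(
      event_log(cur$game, cur$child,
                t = cur$t, kind = cur$kind, target = cur$target,
                meta = cur$meta),
      error = function(e)
        stop("invalid log for child '", cur$child, "' ending at line ",
             cur$last_line, ": ", conditionMessage(e), call. = FALSE))
  }
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop("line ", i, ": malformed JSON", call. = FALSE))
    if (!is.null(rec$game)) {
      if (!is.null(current)) logs[[length(logs) + 1L]] <- flush_current(current)
      current <- list(game = rec$game, child = rec$child %||% "anon",
                      meta = if (is.null(rec$meta)) list()
                             else deserialize_meta(rec$meta),
                      t = numeric(0), kind = character(0),
                      target = character(0), last_line = i)
    } else if (!is.null(rec$t)) {
      if (is.null(current))
        stop("line ", i, ": event before any log header", call. = FALSE)
      if (length(current$t) && rec$t < current$t[length(current$t)])
        stop("line ", i, ": decreasing timestamp", call. = FALSE)
      current$t <- c(current$t, rec$t)
      current$kind <- c(current$kind, rec$kind %||% "")
      current$target <- c(current$target, rec$target %||% "")
      current$last_line <- i
    } else {
      stop("line ", i, ": neither a log header nor an event", call. = FALSE)
    }
  }
  if (!is.null(current)) logs[[length(logs) + 1L]] <- flush_current(current)
  logs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cohort_columns <- function() {
  c("child_id", "group", "age", "sex", "vocabulary_iq",
    outcome_variables()$variable)
}

#' Write a cohort outcome table to CSV
#'
#' Fixed column order: the five demographic columns then the 14 analysis
#' variables; missing values become empty fields.
#'
#' @param table outcome data frame.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_cohort_csv <- function(table, path) {
  cols <- cohort_columns()
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop("table is missing columns: ", paste(miss, collapse = ", "))
  utils::write.csv(table[, cols, drop = FALSE], path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort outcome table from CSV
#'
#' @param path CSV written by [write_cohort_csv()].
#' @return Outcome data frame with the documented columns.
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  miss <- setdiff(cohort_columns(), names(tab))
  if (length(miss))
    stop("cohort CSV is missing columns: ", paste(miss, collapse = ", "))
  tab
}

as_config_list <- function(cfg) {
  out <- unclass(cfg)
  out$dressing_order <- apply(cfg$dressing_order, 1,
                              function(r) as.list(r), simplify = FALSE)
  out
}

game_config_from_list <- function(lst) {
  edges <- lst$dressing_order
  mat <- if (length(edges))
    matrix(unlist(lapply(edges, function(e) c(e$from, e$to))),
           ncol = 2, byrow = TRUE, dimnames = list(NULL, c("from", "to")))
  else default_dressing_order()[0, , drop = FALSE]
  lst$dressing_order <- mat
  do.call(game_config, lst)
}

#' Save / load a run configuration
#'
#' A run configuration bundles the task parameters, the analysis options
#' and the global seed, and round-trips losslessly through YAML.
#'
#' @param cfg a [game_config()].
#' @param path YAML file path.
#' @param seed global seed.
#' @param age_cutoff,winsorize,priors analysis options (see
#'   [run_full_analysis()]).
#' @return `save_run_config` returns the path invisibly; `load_run_config`
#'   returns a list with elements `cfg`, `seed`, `age_cutoff`, `winsorize`,
#'   `priors`.
#' @export
save_run_config <- function(path, cfg = game_config(), seed = 1L,
                            age_cutoff = 6, winsorize = TRUE,
                            priors = "equal") {
  obj <- list(task = as_config_list(cfg), seed = as.integer(seed),
              analysis = list(age_cutoff = age_cutoff,
                              winsorize = winsorize, priors = priors))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  list(cfg = game_config_from_list(obj$task),
       seed = as.integer(obj$seed),
       age_cutoff = obj$analysis$age_cutoff,
       winsorize = obj$analysis$winsorize,
       priors = obj$analysis$priors)
}

#' Serialize a battery report to JSON
#'
#' One object per univariate test (name, statistic, df, p, effect size, n),
#' the age-correlation battery, the discriminant block and the
#' winsorization log.
#'
#' @param report a [run_full_analysis()] result.
#' @param path optional output file; when NULL the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "battery_report"))
  disc <- report$discriminant
  obj <- list(
    n_control_matched = report$n_control_matched,
    n_adhd = report$n_adhd,
    age_correlations = report$age_correlations,
    vocabulary = if (!is.null(report$vocabulary))
      list(test = "t", statistic = report$vocabulary$statistic,
           df = report$vocabulary$df, p = report$vocabulary$p,
           n = report$vocabulary$n),
    discriminant = list(
      wilks_lambda = disc$wilks_lambda, chi2 = disc$chi2, df = disc$df,
      p = disc$p, n = disc$n,
      structure_matrix = as.list(disc$structure_matrix),
      standardized_coefficients = as.list(disc$coefficients),
      confusion = as.vector(disc$confusion),
      sensitivity = disc$sensitivity, specificity = disc$specificity,
      overall = disc$overall),
    group_tests = report$group_tests,
    winsorize_log = report$winsorize_log
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Replicate the full study pipeline end to end
#'
#' One call simulates a cohort with the packaged calibration (default: 96
#' normally developing children aged 4-8 and 40 children with ADHD aged
#' 6-8), scores every event log, compiles the outcome table, and runs the
#' complete analysis chain. Deterministic under the global seed.
#'
#' @param seed global seed, fanned out to all stages.
#' @param n_control,n_adhd cohort sizes.
#' @param cfg a [game_config()].
#' @param out_dir optional directory; when given, the event logs
#'   (`logs.jsonl`), the cohort table (`cohort.csv`) and the analysis
#'   report (`analysis.json`) are written there.
#' @param ... further arguments to [run_full_analysis()].
#' @return List with `cohort` (outcome table) and `report`
#'   ([run_full_analysis()] result).
#' @export
replicate_study <- function(seed = 1L, n_control = 96, n_adhd = 40,
                            cfg = game_config(), out_dir = NULL, ...) {
  if (n_control < 1)
    stop("stage simulate: need at least 1 control child (the ",
         "age-correlation battery runs on the control group)")
  params <- default_calibration(n_control = n_control, n_adhd = n_adhd,
                                seed = seed)
  keep <- !is.null(out_dir)
  cohort <- simulate_cohort(params, cfg, keep_logs = keep)
  report <- tryCatch(run_full_analysis(cohort, ...),
                     error = function(e)
                       stop("stage analyze: ", conditionMessage(e),
                            call. = FALSE))
  if (keep) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    logs <- attr(cohort, "logs")
    write_event_logs(unlist(logs, recursive = FALSE),
                     file.path(out_dir, "logs.jsonl"), cfg)
    attr(cohort, "logs") <- NULL
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    report_to_json(report, file.path(out_dir, "analysis.json"))
  }
  list(cohort = cohort, report = report)
}
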