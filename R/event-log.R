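#' Event log for one child in one mini-game
#'
#' The raw material every scoring engine consumes: an ordered stream of
#' timestamped interaction events. Timestamps are seconds from task start.
#' Event kinds are `click` (any mouse click, including irrelevant ones),
#' `select` (a click that selects a named object, e.g. a garment or an
#' ingredient), `start_hold`/`stop_hold` (the two clicks bounding a balloon
#' inflation attempt) and `end_task` (the child ends the task; at most one,
#' and it must be last).
#'
#' @param game_id one of [game_ids()].
#' @param child_id opaque child identifier.
#' @param t numeric vector of event times (seconds, non-decreasing, >= 0).
#' @param kind character vector of event kinds.
#' @param target character vector of event targets ("" where not applicable).
#' @param meta optional named list of side information attached to the log,
#'   e.g. the realized monkey visibility schedule or the star launch times;
#'   carried through serialization.
#'
#' @return An object of class `event_log`.
#' @examples
#' log <- event_log("rocket", "c1", t = 30, kind = "end_task")
#' score_rocket(log)
#' @export
event_log <- function(game_id, child_id = "anon", t = numeric(0),
                      kind = character(0), target = character(0),
                      meta = list()) {
  n <- length(t)
  if (length(kind) != n)
    stop("t and kind must have equal length")
  if (length(target) == 0) target <- rep("", n)
  if (length(target) != n)
    stop("target must match the number of events")
  log <- structure(
    list(game_id = as.character(game_id),
         child_id = as.character(child_id),
         events = data.frame(t = as.numeric(t), kind = as.character(kind),
                             target = as.character(target),
                             stringsAsFactors = FALSE),
         meta = meta),
    class = "event_log"
  )
  validate_event_log(log)
}

event_kinds <- function() {
  c("click", "select", "start_hold", "stop_hold", "end_task")
}

# Event kinds that count as physical mouse clicks.
click_kinds <- function() {
  c("click", "select", "start_hold", "stop_hold")
}

validate_event_log <- function(log) {
  stopifnot(inherits(log, "event_log"))
  if (!log$game_id %in% game_ids())
    stop("unknown game_id: ", log$game_id)
  ev <- log$events
  if (nrow(ev)) {
    if (any(!ev$kind %in% event_kinds()))
      stop("unknown event kind: ",
           paste(unique(setdiff(ev$kind, event_kinds())), collapse = ", "))
    if (any(ev$t < 0)) stop("timestamps must be >= 0")
    if (is.unsorted(ev$t)) stop("timestamps must be non-decreasing")
    iend <- which(ev$kind == "end_task")
    if (length(iend) > 1) stop("at most one end_task event allowed")
    if (length(iend) == 1 && iend != nrow(ev))
      stop("end_task must be the last event")
  }
  log
}

#' Total number of mouse clicks in a log
#'
#' Counts every physical click event (`click`, `select`, `start_hold`,
#' `stop_hold`); `end_task` is not a click.
#'
#' @param log an [event_log()].
#' @return Integer click count.
#' @export
n_clicks <- function(log) {
  stopifnot(inherits(log, "event_log"))
  sum(log$events$kind %in% click_kinds())
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log> game=", x$game_id, " child=", x$child_id,
      " events=", nrow(x$events), sep = "")
  if (nrow(x$events))
    cat(" span=[0, ", max(x$events$t), "] s", sep = "")
  cat("\n")
  invisible(x)
}

check_game <- function(log, expected) {
  stopifnot(inherits(log, "event_log"))
  if (log$game_id != expected)
    stop(sprintf("log is for game '%s', expected '%s'",
                 log$game_id, expected), call. = FALSE)
  invisible(log)
}
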