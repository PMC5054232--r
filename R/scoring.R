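#' @title Scoring engines for the six mini-games
#' @description
#' Each engine consumes a raw [event_log()] plus the task configuration and
#' returns a `task_score`: the game's primary outcome scores, the total click
#' count, and a completion flag. Scoring is purely deterministic — any
#' randomness (e.g. the monkey's hide-and-seek schedule) enters through the
#' realized schedule recorded alongside the log, never through the scorer.
#' @name scoring
NULL

new_task_score <- function(game_id, scores, n_clicks, complete = NA) {
  structure(list(game_id = game_id, scores = scores,
                 n_clicks = as.integer(n_clicks), complete = complete),
            class = "task_score")
}

#' @export
print.task_score <- function(x, ...) {
  vals <- vapply(x$scores, function(v) format(v, digits = 4), character(1))
  cat("<task_score> ", x$game_id, ": ",
      paste(names(vals), vals, sep = "=", collapse = ", "),
      " | clicks=", x$n_clicks, "\n", sep = "")
  invisible(x)
}

#' Score the dressing-up (planning) task
#'
#' Two points are available: one for being completely dressed (every garment
#' selected at least once) and one for dressing in an executable, correct
#' order (the first selection of each garment respects the dependency partial
#' order, e.g. underwear before trousers). The order point can only be earned
#' together with the completeness point.
#'
#' @param log an [event_log()] with `game_id = "dressing"`.
#' @param cfg a [game_config()].
#' @return A `task_score` with scores `total` (0-2), `complete` (0/1) and
#'   `order` (0/1).
#' @examples
#' log <- ideal_event_log("dressing")
#' score_dressing(log)$scores$total   # 2
#' @export
score_dressing <- function(log, cfg = game_config()) {
  check_game(log, "dressing")
  ev <- log$events
  sel <- ev[ev$kind == "select" & ev$target %in% cfg$dressing_garments, ]
  complete <- all(cfg$dressing_garments %in% sel$target)
  order_ok <- FALSE
  if (complete && !is.null(cfg$dressing_order) && nrow(cfg$dressing_order)) {
    first_idx <- vapply(cfg$dressing_garments,
                        function(g) match(g, sel$target), integer(1))
    names(first_idx) <- cfg$dressing_garments
    order_ok <- all(apply(cfg$dressing_order, 1, function(e) {
      first_idx[e[1]] < first_idx[e[2]]
    }))
  } else if (complete) {
    order_ok <- TRUE
  }
  new_task_score("dressing",
                 list(total = as.integer(complete) + as.integer(order_ok),
                      complete = as.integer(complete),
                      order = as.integer(order_ok)),
                 n_clicks(log), complete = complete)
}

#' Default presented ingredient sequences for the sandwich task
#'
#' One sequence per trial of the configured schedule; trial `i` presents
#' `sandwich_schedule[i]` ingredients, rotated through the ingredient set so
#' consecutive trials differ.
#'
#' @param cfg a [game_config()].
#' @return List of character vectors, one per trial.
#' @export
sandwich_presented <- function(cfg = game_config()) {
  ing <- cfg$sandwich_ingredients
  lapply(seq_along(cfg$sandwich_schedule), function(i) {
    k <- cfg$sandwich_schedule[i]
    ing[((i - 1 + seq_len(k) - 1) %% length(ing)) + 1]
  })
}

#' Score the sandwich (visual working memory) task
#'
#' Per trial the child must reproduce the presented ingredient sequence
#' exactly — same items, same order. One point per exactly reproduced trial.
#' Trials are delimited by a `confirm` click; a trailing unconfirmed
#' selection run counts as the final (incomplete) trial.
#'
#' @param log an [event_log()] with `game_id = "sandwich"`.
#' @param cfg a [game_config()].
#' @param presented list of presented ingredient sequences, one per trial;
#'   defaults to the log's recorded `meta$presented`, else
#'   [sandwich_presented()].
#' @return A `task_score` with scores `total` (0 to number of trials) and
#'   `n_trials`.
#' @export
score_sandwich <- function(log, cfg = game_config(), presented = NULL) {
  check_game(log, "sandwich")
  if (is.null(presented)) presented <- log$meta$presented
  if (is.null(presented)) presented <- sandwich_presented(cfg)
  ev <- log$events
  trials <- list()
  current <- character(0)
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]
    if (k == "select") {
      current <- c(current, ev$target[i])
    } else if (k == "click" && ev$target[i] == "confirm") {
      trials[[length(trials) + 1L]] <- current
      current <- character(0)
    }
  }
  if (length(current)) trials[[length(trials) + 1L]] <- current
  if (length(trials) > length(presented))
    stop("log contains more trials (", length(trials),
         ") than the schedule (", length(presented), ")")
  correct <- vapply(seq_along(trials), function(i) {
    identical(as.character(trials[[i]]), as.character(presented[[i]]))
  }, logical(1))
  new_task_score("sandwich",
                 list(total = sum(correct), n_trials = length(trials)),
                 n_clicks(log),
                 complete = length(trials) == length(presented))
}

#' Score the monkey (go/no-go inhibition) task
#'
#' The child swipes banana peels off the road but must withhold swiping
#' while the monkey is watching. A swipe during a visible interval is a
#' failure — the monkey undoes it, so it does not remove a peel; a swipe
#' during a hidden interval removes one peel. The task is complete once the
#' configured number of peels has been cleared. The number of failures is
#' the primary outcome; the higher, the worse the response inhibition.
#'
#' @param log an [event_log()] with `game_id = "monkey"`. Swipes are `click`
#'   or `select` events with target `"peel"`.
#' @param schedule data frame of disjoint visible intervals (`start`, `end`,
#'   closed); defaults to the log's recorded `meta$monkey_schedule`.
#' @param cfg a [game_config()].
#' @return A `task_score` with scores `failures` and `successes`.
#' @export
score_monkey <- function(log, schedule = NULL, cfg = game_config()) {
  check_game(log, "monkey")
  if (is.null(schedule)) schedule <- log$meta$monkey_schedule
  if (is.null(schedule))
    schedule <- data.frame(start = numeric(0), end = numeric(0))
  schedule <- as.data.frame(schedule)
  ev <- log$events
  swipes <- ev$t[ev$kind %in% c("click", "select") & ev$target == "peel"]
  visible <- vapply(swipes, function(t)
    any(t >= schedule$start & t <= schedule$end), logical(1))
  failures <- sum(visible)
  successes <- sum(!visible)
  new_task_score("monkey",
                 list(failures = failures, successes = successes),
                 n_clicks(log),
                 complete = successes >= cfg$monkey_peels)
}

#' Score the magic-land (simple reaction time) task
#'
#' Stars shoot up from magic holes one after another; each star rises for
#' `magicland_rise` seconds and then remains catchable for
#' `magicland_window` seconds before disappearing. A star is collected if a
#' click credited to it lands in `[launch, launch + rise + window]`; each
#' click is credited to at most one star, and an untargeted click credits
#' the earliest still-uncollected star whose span contains it. The reaction
#' time of a collected star is the click time minus the launch time.
#'
#' @param log an [event_log()] with `game_id = "magicland"`. Clicks with
#'   target `"star<k>"` are credited only to star `k`; clicks with empty
#'   target or target `"star"` are credited to the earliest eligible star;
#'   clicks with target `"none"` never collect.
#' @param star_schedule numeric vector of launch times; defaults to the
#'   log's recorded `meta$star_schedule`, else [magicland_star_schedule()].
#' @param cfg a [game_config()].
#' @return A `task_score` with scores `collected`, `missed` and `mean_rt`
#'   (NA when no star was collected).
#' @export
score_magic_land <- function(log, star_schedule = NULL, cfg = game_config()) {
  check_game(log, "magicland")
  if (is.null(star_schedule)) star_schedule <- log$meta$star_schedule
  if (is.null(star_schedule)) star_schedule <- magicland_star_schedule(cfg)
  star_schedule <- as.numeric(star_schedule)
  if (is.unsorted(star_schedule, strictly = TRUE))
    stop("star_schedule must be strictly increasing")
  span <- cfg$magicland_rise + cfg$magicland_window
  ev <- log$events
  clk <- ev[ev$kind %in% c("click", "select"), , drop = FALSE]
  collected_by <- rep(NA_real_, length(star_schedule))
  for (i in seq_len(nrow(clk))) {
    tg <- clk$target[i]
    t <- clk$t[i]
    if (tg == "none") next
    if (grepl("^star[0-9]+$", tg)) {
      k <- as.integer(sub("^star", "", tg))
      if (k >= 1 && k <= length(star_schedule) && is.na(collected_by[k]) &&
          t >= star_schedule[k] && t <= star_schedule[k] + span)
        collected_by[k] <- t
    } else if (tg == "" || tg == "star") {
      elig <- which(is.na(collected_by) &
                      t >= star_schedule & t <= star_schedule + span)
      if (length(elig)) collected_by[elig[1]] <- t
    }
  }
  hit <- !is.na(collected_by)
  mean_rt <- if (any(hit)) mean(collected_by[hit] - star_schedule[hit])
             else NA_real_
  new_task_score("magicland",
                 list(collected = sum(hit),
                      missed = sum(!hit),
                      mean_rt = mean_rt),
                 n_clicks(log), complete = TRUE)
}

#' Score the rocket (delay aversion) task
#'
#' The child chooses between a small immediate reward (ending the task now)
#' and a large delayed reward (a rocket flight after the full wait). The
#' recorded wait is the time of the `end_task` event, capped at the maximum;
#' a child who never ends the task waits the full time and earns the large
#' reward. `choice` is 1 (large) exactly when the full wait was reached.
#'
#' @param log an [event_log()] with `game_id = "rocket"`.
#' @param cfg a [game_config()].
#' @return A `task_score` with scores `choice` (0 small / 1 large) and
#'   `wait` (seconds).
#' @export
score_rocket <- function(log, cfg = game_config()) {
  check_game(log, "rocket")
  ev <- log$events
  iend <- which(ev$kind == "end_task")
  wait <- if (length(iend)) min(ev$t[iend], cfg$rocket_max_wait)
          else cfg$rocket_max_wait
  new_task_score("rocket",
                 list(choice = as.integer(wait >= cfg$rocket_max_wait),
                      wait = wait),
                 n_clicks(log), complete = TRUE)
}

#' Score the balloon (time production) task
#'
#' The child inflates balloons by holding for a target interval of 10
#' seconds; an interval inside the closed window `[9, 11]` s makes a perfect
#' balloon. The task ends after 3 perfect balloons or at the timeout (the
#' story then grants a progress balloon that is not counted as correct).
#' The timing-precision outcome is the mean absolute deviation from the
#' target over the first `min(3, n_attempts)` attempts.
#'
#' @param log an [event_log()] with `game_id = "balloon"`; attempts are
#'   consecutive `start_hold`/`stop_hold` pairs.
#' @param cfg a [game_config()].
#' @return A `task_score` with scores `correct` (0-3), `n_attempts` and
#'   `mean_abs_error` (seconds; NA when no attempt was made).
#' @export
score_balloon <- function(log, cfg = game_config()) {
  check_game(log, "balloon")
  ev <- log$events
  holds <- ev[ev$kind %in% c("start_hold", "stop_hold"), , drop = FALSE]
  open_at <- NA_real_
  intervals <- numeric(0)
  for (i in seq_len(nrow(holds))) {
    if (holds$kind[i] == "start_hold") {
      if (!is.na(open_at)) stop("malformed log: start_hold while holding")
      open_at <- holds$t[i]
    } else {
      if (is.na(open_at)) stop("malformed log: stop_hold without start_hold")
      intervals <- c(intervals, holds$t[i] - open_at)
      open_at <- NA_real_
    }
  }
  w <- cfg$balloon_window
  is_correct <- intervals >= w[1] & intervals <= w[2]
  correct <- min(sum(is_correct), cfg$balloon_max_correct)
  k <- min(cfg$balloon_max_correct, length(intervals))
  mae <- if (k > 0) mean(abs(intervals[seq_len(k)] - cfg$balloon_target))
         else NA_real_
  last_t <- if (nrow(ev)) max(ev$t) else 0
  new_task_score("balloon",
                 list(correct = correct,
                      n_attempts = length(intervals),
                      mean_abs_error = mae),
                 n_clicks(log),
                 complete = correct >= cfg$balloon_max_correct ||
                   last_t >= cfg$balloon_timeout)
}

#' Score any mini-game log by its game id
#'
#' Dispatches to the matching engine.
#'
#' @param log an [event_log()].
#' @param cfg a [game_config()].
#' @return A `task_score`.
#' @export
score_log <- function(log, cfg = game_config()) {
  switch(log$game_id,
         dressing  = score_dressing(log, cfg),
         sandwich  = score_sandwich(log, cfg),
         monkey    = score_monkey(log, cfg = cfg),
         magicland = score_magic_land(log, cfg = cfg),
         rocket    = score_rocket(log, cfg),
         balloon   = score_balloon(log, cfg),
         stop("unknown game_id: ", log$game_id))
}

#' The 14 analysis outcome variables
#'
#' Column metadata for the analysis table: variable name, source game,
#' measurement scale (`scale` vs `ordinal`, which decides Pearson vs
#' Spearman in the age-correlation battery) and whether the variable is
#' treated as categorical in the group comparisons (chi-square association
#' instead of a mean test).
#'
#' @return Data frame with columns `variable`, `game`, `scale`,
#'   `categorical`, 14 rows in the fixed analysis order.
#' @export
outcome_variables <- function() {
  data.frame(
    variable = c("dressing_total", "dressing_clicks",
                 "sandwich_total", "sandwich_clicks",
                 "balloon_clicks",
                 "monkey_failures", "monkey_clicks",
                 "magicland_stars", "magicland_mean_rt", "magicland_clicks",
                 "rocket_choice", "rocket_wait",
                 "balloon_correct", "balloon_mean_abs_error"),
    game = c("dressing", "dressing", "sandwich", "sandwich", "balloon",
             "monkey", "monkey", "magicland", "magicland", "magicland",
             "rocket", "rocket", "balloon", "balloon"),
    scale = c("ordinal", "scale", "ordinal", "scale", "scale",
              "scale", "scale", "scale", "scale", "scale",
              "ordinal", "scale", "ordinal", "scale"),
    categorical = c(TRUE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, FALSE, FALSE,
                    TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Compile six task scores into one outcome row
#'
#' Assembles the 14 analysis variables, in the fixed order given by
#' [outcome_variables()], from exactly one `task_score` per game, prefixed
#' by the demographic columns. Missing sub-scores (e.g. mean reaction time
#' when no star was collected) propagate as NA.
#'
#' @param scores list of six `task_score` objects, one per game.
#' @param child_id,group,age,sex,vocabulary_iq demographics; `group` must be
#'   `"control"` or `"adhd"` (or NA for unlabeled data).
#' @return One-row data frame: `child_id`, `group`, `age`, `sex`,
#'   `vocabulary_iq`, then the 14 analysis variables.
#' @export
compile_outcomes <- function(scores, child_id = "anon", group = NA,
                             age = NA_real_, sex = NA_character_,
                             vocabulary_iq = NA_real_) {
  ids <- vapply(scores, function(s) {
    stopifnot(inherits(s, "task_score"))
    s$game_id
  }, character(1))
  if (anyDuplicated(ids))
    stop("duplicate task score for game: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing <- setdiff(game_ids(), ids)
  if (length(missing))
    stop("missing task score for game: ", paste(missing, collapse = ", "))
  if (!is.na(group) && !group %in% c("control", "adhd"))
    stop("group must be 'control' or 'adhd'")
  s <- stats::setNames(scores, ids)
  na_or <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
  data.frame(
    child_id = as.character(child_id),
    group = as.character(group),
    age = as.numeric(age),
    sex = as.character(sex),
    vocabulary_iq = as.numeric(vocabulary_iq),
    dressing_total = s$dressing$scores$total,
    dressing_clicks = s$dressing$n_clicks,
    sandwich_total = s$sandwich$scores$total,
    sandwich_clicks = s$sandwich$n_clicks,
    balloon_clicks = s$balloon$n_clicks,
    monkey_failures = s$monkey$scores$failures,
    monkey_clicks = s$monkey$n_clicks,
    magicland_stars = s$magicland$scores$collected,
    magicland_mean_rt = na_or(s$magicland$scores$mean_rt),
    magicland_clicks = s$magicland$n_clicks,
    rocket_choice = s$rocket$scores$choice,
    rocket_wait = s$rocket$scores$wait,
    balloon_correct = s$balloon$scores$correct,
    balloon_mean_abs_error = na_or(s$balloon$scores$mean_abs_error),
    stringsAsFactors = FALSE
  )
}

#' Ideal (minimal, perfect) event log for a game
#'
#' Constructs the event log of a hypothetical perfect responder who solves
#' the task with no wasted clicks: it realizes the battery's minimal-click
#' solutions (4 clicks to dress, 22 clicks for five correct sandwiches under
#' the default schedule, 6 swipes for the monkey, one in-window click per
#' star, no quitting in the rocket task, and three exactly-on-target
#' balloons for 6 clicks).
#'
#' @param game one of [game_ids()].
#' @param cfg a [game_config()].
#' @param child_id child identifier for the log.
#' @return An [event_log()].
#' @export
ideal_event_log <- function(game, cfg = game_config(), child_id = "ideal") {
  game <- match.arg(game, game_ids())
  switch(game,
    dressing = {
      ord <- topological_order(cfg$dressing_garments, cfg$dressing_order)
      event_log("dressing", child_id,
                t = seq_along(ord), kind = rep("select", length(ord)),
                target = ord)
    },
    sandwich = {
      pres <- sandwich_presented(cfg)
      t <- 0; ts <- numeric(0); kind <- character(0); target <- character(0)
      for (p in pres) {
        for (ing in p) {
          t <- t + 1
          ts <- c(ts, t); kind <- c(kind, "select"); target <- c(target, ing)
        }
        t <- t + 1
        ts <- c(ts, t); kind <- c(kind, "click"); target <- c(target, "confirm")
      }
      event_log("sandwich", child_id, t = ts, kind = kind, target = target,
                meta = list(presented = pres))
    },
    monkey = {
      # hidden on [10k, 10k+5), visible on [10k+5, 10k+8]; swipe mid-hidden
      n <- cfg$monkey_peels
      sched <- data.frame(start = 10 * (seq_len(n) - 1) + 5,
                          end = 10 * (seq_len(n) - 1) + 8)
      event_log("monkey", child_id,
                t = 10 * (seq_len(n) - 1) + 2,
                kind = rep("click", n), target = rep("peel", n),
                meta = list(monkey_schedule = sched))
    },
    magicland = {
      launches <- magicland_star_schedule(cfg)
      event_log("magicland", child_id,
                t = launches + 0.5,
                kind = rep("click", length(launches)),
                target = paste0("star", seq_along(launches)),
                meta = list(star_schedule = launches))
    },
    rocket = event_log("rocket", child_id),
    balloon = {
      n <- cfg$balloon_max_correct
      tgt <- cfg$balloon_target
      starts <- (tgt + 2) * (seq_len(n) - 1)
      ts <- as.vector(rbind(starts, starts + tgt))
      event_log("balloon", child_id,
                t = ts,
                kind = rep(c("start_hold", "stop_hold"), n))
    })
}

# Deterministic topological order of garments honoring the dependency edges.
topological_order <- function(nodes, edges) {
  if (is.null(edges) || nrow(edges) == 0) return(nodes)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) indeg[edges[i, 2]] <- indeg[edges[i, 2]] + 1L
  out <- character(0)
  remaining <- nodes
  while (length(remaining)) {
    ready <- remaining[indeg[remaining] == 0L]
    if (!length(ready)) stop("dependency order has a cycle")
    n <- ready[1]
    out <- c(out, n)
    remaining <- setdiff(remaining, n)
    succ <- edges[edges[, 1] == n, 2]
    indeg[succ] <- indeg[succ] - 1L
  }
  out
}
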