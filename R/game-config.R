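#' Mini-game identifiers
#'
#' The six tasks of the battery, one per measured construct: `dressing`
#' (planning), `sandwich` (visual working memory), `monkey` (response
#' inhibition, go/no-go), `magicland` (simple reaction time), `rocket`
#' (delay aversion) and `balloon` (time production).
#'
#' @return Character vector of the six game identifiers, in battery order.
#' @export
game_ids <- function() {
  c("dressing", "sandwich", "monkey", "magicland", "rocket", "balloon")
}

#' Task configuration for the six mini-games
#'
#' Bundles every tunable task parameter. The defaults reproduce the battery's
#' published task constants: a 4-garment dressing task whose minimal correct
#' solution is 4 clicks; a 5-sandwich working-memory task whose ingredient
#' counts run from 2 up to 5 with a minimal-click solution of 22; a monkey
#' go/no-go task needing 6 successful swipes; a 50-star reaction-time task
#' with a 2-second response window; a 120-second maximum wait for the delayed
#' rocket reward; and a 10-second time-production target scored correct on
#' the closed interval [9, 11] seconds, capped at 3 correct balloons with a
#' 180-second task timeout.
#'
#' @param dressing_garments character vector of garment ids.
#' @param dressing_order two-column character matrix of dependency edges
#'   (`from` must be put on before `to`). Defaults to under-layers before
#'   outer-layers: underwear before trousers, shirt before jacket.
#' @param sandwich_schedule integer vector of per-trial ingredient counts;
#'   must start at 2 and end at 5.
#' @param sandwich_ingredients character vector of available ingredient ids.
#' @param monkey_peels number of banana peels, i.e. successful (hidden-phase)
#'   swipes required to finish.
#' @param monkey_hidden,monkey_visible length-2 numeric ranges (seconds) from
#'   which alternating hidden/visible phase durations are drawn when a
#'   visibility schedule is generated.
#' @param magicland_n_stars number of stars launched before the task ends.
#' @param magicland_window response window per star, seconds, counted from the
#'   moment the star is fully risen.
#' @param magicland_rise star rise/animation duration in seconds; the star is
#'   clickable from launch, and reaction times are measured from launch, so
#'   the clickable span per star is `magicland_rise + magicland_window`.
#' @param magicland_isi inter-stimulus interval between star launches, seconds.
#' @param rocket_max_wait maximum recordable wait, seconds; waiting this long
#'   yields the large delayed reward.
#' @param balloon_target target production interval, seconds.
#' @param balloon_window closed numeric interval `c(low, high)` of intervals
#'   accepted as a perfect balloon.
#' @param balloon_max_correct perfect balloons after which the task ends.
#' @param balloon_timeout task timeout in seconds; at timeout the story grants
#'   a progress balloon that is not counted as correct.
#'
#' @return An object of class `game_config` (a validated named list).
#' @examples
#' cfg <- game_config()
#' cfg$sandwich_schedule   # 2 3 3 4 5
#' @export
game_config <- function(dressing_garments = c("underwear", "shirt",
                                              "trousers", "jacket"),
                        dressing_order = default_dressing_order(),
                        sandwich_schedule = c(2L, 3L, 3L, 4L, 5L),
                        sandwich_ingredients = paste0("ing", 1:8),
                        monkey_peels = 6L,
                        monkey_hidden = c(2, 5),
                        monkey_visible = c(1, 3),
                        magicland_n_stars = 50L,
                        magicland_window = 2,
                        magicland_rise = 1.5,
                        magicland_isi = 3,
                        rocket_max_wait = 120,
                        balloon_target = 10,
                        balloon_window = c(9, 11),
                        balloon_max_correct = 3L,
                        balloon_timeout = 180) {
  cfg <- structure(
    list(
      dressing_garments = as.character(dressing_garments),
      dressing_order = dressing_order,
      sandwich_schedule = as.integer(sandwich_schedule),
      sandwich_ingredients = as.character(sandwich_ingredients),
      monkey_peels = as.integer(monkey_peels),
      monkey_hidden = as.numeric(monkey_hidden),
      monkey_visible = as.numeric(monkey_visible),
      magicland_n_stars = as.integer(magicland_n_stars),
      magicland_window = as.numeric(magicland_window),
      magicland_rise = as.numeric(magicland_rise),
      magicland_isi = as.numeric(magicland_isi),
      rocket_max_wait = as.numeric(rocket_max_wait),
      balloon_target = as.numeric(balloon_target),
      balloon_window = as.numeric(balloon_window),
      balloon_max_correct = as.integer(balloon_max_correct),
      balloon_timeout = as.numeric(balloon_timeout)
    ),
    class = "game_config"
  )
  validate_game_config(cfg)
}

#' @rdname game_config
#' @export
default_dressing_order <- function() {
  matrix(c("underwear", "trousers",
           "shirt", "jacket"),
         ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("from", "to")))
}

validate_game_config <- function(cfg) {
  stopifnot(inherits(cfg, "game_config"))
  if (length(cfg$dressing_garments) < 1 ||
      anyDuplicated(cfg$dressing_garments))
    stop("dressing_garments must be a non-empty set of unique ids")
  ord <- cfg$dressing_order
  if (!is.null(ord)) {
    if (!is.matrix(ord) || ncol(ord) != 2)
      stop("dressing_order must be a two-column matrix of edges")
    if (!all(ord %in% cfg$dressing_garments))
      stop("dressing_order refers to unknown garments")
    if (has_cycle(cfg$dressing_garments, ord))
      stop("dressing_order must be a partial order (no cycles)")
  }
  sched <- cfg$sandwich_schedule
  if (length(sched) < 1 || sched[1] != 2L || sched[length(sched)] != 5L)
    stop("sandwich_schedule must be non-empty, starting at 2 and ending at 5")
  if (any(sched < 1) || any(diff(sched) < 0))
    stop("sandwich_schedule must be non-decreasing positive counts")
  if (max(sched) > length(cfg$sandwich_ingredients))
    stop("not enough sandwich_ingredients for the longest trial")
  if (cfg$monkey_peels < 1) stop("monkey_peels must be >= 1")
  if (any(cfg$monkey_hidden <= 0) || any(cfg$monkey_visible <= 0) ||
      length(cfg$monkey_hidden) != 2 || length(cfg$monkey_visible) != 2 ||
      diff(cfg$monkey_hidden) < 0 || diff(cfg$monkey_visible) < 0)
    stop("monkey phase duration ranges must be positive c(low, high)")
  if (cfg$magicland_n_stars < 1) stop("magicland_n_stars must be >= 1")
  if (cfg$magicland_window <= 0 || cfg$magicland_isi <= 0 ||
      cfg$magicland_rise < 0)
    stop("magicland durations must be positive (rise may be 0)")
  if (cfg$rocket_max_wait <= 0) stop("rocket_max_wait must be > 0")
  w <- cfg$balloon_window
  if (length(w) != 2 || w[1] > w[2])
    stop("balloon_window must be c(low, high) with low <= high")
  if (cfg$balloon_target < w[1] || cfg$balloon_target > w[2])
    stop("balloon_window must contain balloon_target")
  if (cfg$balloon_max_correct < 1 || cfg$balloon_timeout <= 0)
    stop("balloon_max_correct must be >= 1 and balloon_timeout > 0")
  cfg
}

# Kahn's algorithm; TRUE if the edge set has a directed cycle.
has_cycle <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) indeg[edges[i, 2]] <- indeg[edges[i, 2]] + 1L
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    out <- edges[edges[, 1] == n, 2]
    for (m in out) {
      indeg[m] <- indeg[m] - 1L
      if (indeg[m] == 0L) queue <- c(queue, m)
    }
  }
  seen < length(nodes)
}

#' @export
print.game_config <- function(x, ...) {
  cat("<game_config>\n")
  cat("  dressing : ", length(x$dressing_garments), " garments, ",
      nrow(x$dressing_order), " order constraints\n", sep = "")
  cat("  sandwich : schedule ", paste(x$sandwich_schedule, collapse = "-"),
      " (minimal clicks ", sum(x$sandwich_schedule) +
        length(x$sandwich_schedule), ")\n", sep = "")
  cat("  monkey   : ", x$monkey_peels, " peels\n", sep = "")
  cat("  magicland: ", x$magicland_n_stars, " stars, window ",
      x$magicland_window, " s after ", x$magicland_rise, " s rise, ISI ",
      x$magicland_isi, " s\n", sep = "")
  cat("  rocket   : max wait ", x$rocket_max_wait, " s\n", sep = "")
  cat("  balloon  : target ", x$balloon_target, " s in [",
      x$balloon_window[1], ", ", x$balloon_window[2], "], max ",
      x$balloon_max_correct, " correct, timeout ", x$balloon_timeout,
      " s\n", sep = "")
  invisible(x)
}

#' Star launch schedule for the reaction-time task
#'
#' Launch times are evenly spaced at the configured inter-stimulus interval,
#' starting at `start`.
#'
#' @param cfg a [game_config()].
#' @param start launch time of the first star, seconds.
#' @return Numeric vector of strictly increasing launch times.
#' @export
magicland_star_schedule <- function(cfg = game_config(), start = 0) {
  start + cfg$magicland_isi * (seq_len(cfg$magicland_n_stars) - 1)
}

#' Monkey visibility schedule
#'
#' The monkey plays hide-and-seek: the task alternates hidden phases (swipes
#' succeed) and visible phases (swipes fail and are undone). Phase durations
#' are drawn uniformly from the configured ranges. Scoring consumes the
#' realized schedule, so scoring itself stays deterministic.
#'
#' @param cfg a [game_config()].
#' @param total_time schedule horizon in seconds.
#' @param seed optional integer seed for reproducibility.
#' @return Data frame with columns `start`, `end`: the disjoint visible
#'   intervals, in increasing order.
#' @export
monkey_visibility_schedule <- function(cfg = game_config(), total_time = 120,
                                       seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  t <- 0
  starts <- numeric(0)
  ends <- numeric(0)
  repeat {
    t <- t + stats::runif(1, cfg$monkey_hidden[1], cfg$monkey_hidden[2])
    if (t >= total_time) break
    vis <- stats::runif(1, cfg$monkey_visible[1], cfg$monkey_visible[2])
    starts <- c(starts, t)
    ends <- c(ends, min(t + vis, total_time))
    t <- t + vis
    if (t >= total_time) break
  }
  data.frame(start = starts, end = ends)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
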