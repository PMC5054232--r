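#' Population parameters for the responder simulator
#'
#' Per-group latent-trait distribution parameters for the generative model
#' of child responders. The model follows the triple-pathway account of
#' ADHD: an inhibitory/executive pathway (planning success, working-memory
#' span with its age anchors of 3 items at age 3 and 5 items at age 7,
#' go/no-go failure rate, lognormal reaction times), a reward pathway
#' (probability of committing to the delayed reward, mean tolerable wait),
#' and a timing pathway (Gaussian production noise around the 10-s target).
#' Irrelevant-click propensities are per-task Poisson means with a shared
#' lognormal child-level multiplier.
#'
#' @param n_control,n_adhd cohort sizes.
#' @param age_range_control,age_range_adhd sampled age ranges in years.
#' @param control,adhd named lists of group trait parameters (see
#'   [default_calibration()] for the full set and packaged values).
#' @param seed integer seed reproducing the cohort bit-identically.
#' @return An object of class `population_params`.
#' @export
population_params <- function(n_control = 96, n_adhd = 40,
                              age_range_control = c(4, 8),
                              age_range_adhd = c(6, 8),
                              control, adhd, seed = 1L) {
  stopifnot(n_control >= 0, n_adhd >= 0)
  for (g in list(control, adhd)) {
    if (g$timing_sd <= 0) stop("timing_sd must be > 0")
    if (g$speed_sdlog <= 0) stop("speed_sdlog must be > 0")
    probs <- c(g$dress_complete_p, g$dress_order_p, g$seq_accuracy,
               g$delay_commit_p)
    if (any(probs < 0 | probs > 1))
      stop("probability parameters must lie in [0, 1]")
    if (any(c(g$dress_extra, g$sandwich_extra, g$monkey_extra,
              g$balloon_extra, g$magicland_click_rate) < 0))
      stop("click-rate parameters must be >= 0")
  }
  structure(list(n_control = as.integer(n_control),
                 n_adhd = as.integer(n_adhd),
                 age_range_control = as.numeric(age_range_control),
                 age_range_adhd = as.numeric(age_range_adhd),
                 control = control, adhd = adhd,
                 seed = as.integer(seed)),
            class = "population_params")
}

#' Packaged default calibration of the responder simulator
#'
#' Hand-tuned moment-matching defaults: with these parameters, simulated
#' control responders aged 6-8 and ADHD responders reproduce the battery's
#' published group means of all 14 outcome variables to within half a
#' pooled SD, and simulated controls aged 4-8 reproduce the signs of the
#' significant developmental correlations (fewer go/no-go failures, faster
#' reaction times, more collected stars, more correct balloons and smaller
#' production error with increasing age). Age enters each trait linearly on
#' its latent scale, with the working-memory span anchored at 3 items at
#' age 3 and 5 items at age 7.
#'
#' @param n_control,n_adhd cohort sizes (defaults: the study sizes 96/40).
#' @param seed integer seed.
#' @return A [population_params()] object.
#' @export
default_calibration <- function(n_control = 96, n_adhd = 40, seed = 1L) {
  shared <- list(
    span_at3 = 3, span_slope = 0.5, span_trial_sd = 0.8,
    inhibit_slope = -0.25, inhibit_sd = 0.4,
    speed_slope = -0.08, speed_between = 0.15,
    timing_slope = -0.6, timing_min = 0.8,
    extra_sdlog = 0.5, monkey_extra_sdlog = 0.1,
    sex_male_p = 0.448, iq_mean = 94.74, iq_sd = 10.79
  )
  control <- utils::modifyList(shared, list(
    dress_complete_p = 0.85, dress_order_p = 0.39, dress_extra = 13.7,
    seq_accuracy = 0.59, sandwich_extra = 65.5,
    inhibit_logit = -2.05, monkey_extra = 23.0,
    speed_meanlog = 0.946, speed_sdlog = 0.45,
    magicland_click_rate = 0.525,
    delay_commit_p = 0.55, delay_tolerance = 39,
    timing_sd = 5.43, balloon_extra = 80,
    sex_male_p = 43 / 96, iq_mean = 94.74, iq_sd = 10.79
  ))
  adhd <- utils::modifyList(shared, list(
    dress_complete_p = 0.75, dress_order_p = 0.24, dress_extra = 22.4,
    seq_accuracy = 0.625, sandwich_extra = 70.6,
    inhibit_logit = -1.60, monkey_extra = 26.6,
    speed_meanlog = 0.874, speed_sdlog = 0.40,
    magicland_click_rate = 2.11,
    delay_commit_p = 0.28, delay_tolerance = 36,
    timing_sd = 4.24, balloon_extra = 177,
    sex_male_p = 30 / 40, iq_mean = 87.92, iq_sd = 13.05
  ))
  population_params(n_control = n_control, n_adhd = n_adhd,
                    control = control, adhd = adhd, seed = seed)
}

#' Sample a cohort of child profiles
#'
#' Draws per-child demographics (age uniform in the group range, sex,
#' verbal IQ) and realized latent traits, applying the age slopes on each
#' trait's latent scale. Deterministic under the parameter object's seed.
#'
#' @param params a [population_params()].
#' @return Data frame of child profiles, one row per child (class
#'   `child_profiles`): demographics plus the realized traits consumed by
#'   [simulate_child()].
#' @export
sample_cohort <- function(params) {
  stopifnot(inherits(params, "population_params"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(params$seed)
  one_group <- function(n, group, range, g, id_prefix) {
    if (n == 0) return(NULL)
    age <- stats::runif(n, range[1], range[2])
    mult <- function(m) m * stats::rlnorm(n, -g$extra_sdlog^2 / 2,
                                          g$extra_sdlog)
    jit_logit <- function(p, sd = 0.3)
      stats::plogis(stats::qlogis(p) + stats::rnorm(n, 0, sd))
    data.frame(
      child_id = sprintf("%s%03d", id_prefix, seq_len(n)),
      group = group,
      age = age,
      sex = ifelse(stats::runif(n) < g$sex_male_p, "m", "f"),
      vocabulary_iq = round(stats::rnorm(n, g$iq_mean, g$iq_sd)),
      dress_complete_p = jit_logit(g$dress_complete_p),
      dress_order_p = jit_logit(g$dress_order_p),
      wm_span = g$span_at3 + g$span_slope * (age - 3),
      seq_accuracy = jit_logit(g$seq_accuracy, 0.2),
      span_trial_sd = g$span_trial_sd,
      inhibition_fail_rate = stats::plogis(
        g$inhibit_logit + g$inhibit_slope * (age - 7) +
          stats::rnorm(n, 0, g$inhibit_sd)),
      speed_mu = g$speed_meanlog + g$speed_slope * (age - 7) +
        stats::rnorm(n, 0, g$speed_between),
      speed_sigma = g$speed_sdlog,
      timing_sd = pmax(g$timing_min,
                       g$timing_sd + g$timing_slope * (age - 7) +
                         stats::rnorm(n, 0, 0.5)),
      delay_commit_p = g$delay_commit_p,
      delay_tolerance = g$delay_tolerance,
      dress_extra = mult(g$dress_extra),
      sandwich_extra = mult(g$sandwich_extra),
      # published click dispersion in the go/no-go task is far tighter than
      # elsewhere, so its child-level heterogeneity is kept low
      monkey_extra = g$monkey_extra *
        stats::rlnorm(n, -g$monkey_extra_sdlog^2 / 2, g$monkey_extra_sdlog),
      balloon_extra = mult(g$balloon_extra),
      magicland_click_rate = mult(g$magicland_click_rate),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(one_group(params$n_control, "control",
                         params$age_range_control, params$control, "ctl"),
               one_group(params$n_adhd, "adhd",
                         params$age_range_adhd, params$adhd, "adh"))
  class(out) <- c("child_profiles", class(out))
  out
}

#' Simulate the six event logs of one child
#'
#' Behavioral realization of a child profile: garment order respects the
#' dependency order with the planning probability; a sandwich trial is
#' reproduced exactly when its length is within the child's realized span
#' and every item is executed correctly; each monkey swipe lands in a
#' visible interval with the inhibition failure rate; per-star reaction
#' times are lognormal and a star is collected when the reaction beats the
#' window; the rocket wait is a point mass at the full wait (delayed-reward
#' commitment) mixed with a truncated-exponential quit time; balloon
#' production intervals are Gaussian around the target until three correct
#' or timeout. Irrelevant clicks are Poisson with the child's per-task
#' propensities.
#'
#' @param profile one row of [sample_cohort()] (or an equivalent named
#'   list).
#' @param cfg a [game_config()].
#' @param seed integer seed; the same (profile, cfg, seed) always yields
#'   identical logs.
#' @return Named list of six [event_log()] objects.
#' @export
simulate_child <- function(profile, cfg = game_config(), seed = 1L) {
  pr <- as.list(profile)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  logs <- list(
    dressing = sim_dressing(pr, cfg),
    sandwich = sim_sandwich(pr, cfg),
    monkey = sim_monkey(pr, cfg),
    magicland = sim_magicland(pr, cfg),
    rocket = sim_rocket(pr, cfg),
    balloon = sim_balloon(pr, cfg)
  )
  logs
}

# interleave irrelevant "none" clicks into an event stream, keeping time order
add_irrelevant <- function(t, kind, target, n_extra, horizon) {
  if (n_extra > 0) {
    te <- sort(stats::runif(n_extra, 0, horizon))
    t <- c(t, te)
    kind <- c(kind, rep("click", n_extra))
    target <- c(target, rep("none", n_extra))
    ord <- order(t)
    t <- t[ord]; kind <- kind[ord]; target <- target[ord]
  }
  list(t = t, kind = kind, target = target)
}

sim_dressing <- function(pr, cfg) {
  garments <- cfg$dressing_garments
  ord <- topological_order(garments, cfg$dressing_order)
  complete <- stats::runif(1) < pr$dress_complete_p
  good_order <- stats::runif(1) < pr$dress_order_p
  if (!good_order && !is.null(cfg$dressing_order) &&
      nrow(cfg$dressing_order)) {
    e <- cfg$dressing_order[sample(nrow(cfg$dressing_order), 1), ]
    i <- match(e[1], ord); j <- match(e[2], ord)
    ord[c(i, j)] <- ord[c(j, i)]           # violate one dependency edge
  }
  if (!complete) ord <- ord[-sample(length(ord), 1)]
  t <- 2 * seq_along(ord)
  horizon <- max(t, 2) + 5
  ev <- add_irrelevant(t, rep("select", length(ord)), ord,
                       stats::rpois(1, pr$dress_extra), horizon)
  event_log("dressing", pr$child_id, ev$t, ev$kind, ev$target)
}

sim_sandwich <- function(pr, cfg) {
  pres <- sandwich_presented(cfg)
  t <- 0; ts <- numeric(0); kind <- character(0); target <- character(0)
  for (p in pres) {
    len <- length(p)
    span_ok <- len <= pr$wm_span + stats::rnorm(1, 0, pr$span_trial_sd)
    exec_ok <- stats::runif(1) < pr$seq_accuracy^len
    ans <- p
    if (!(span_ok && exec_ok)) {
      if (len >= 2) {
        i <- sample(len - 1, 1)
        ans[c(i, i + 1)] <- ans[c(i + 1, i)]  # transpose two items
      } else {
        ans <- setdiff(cfg$sandwich_ingredients, p)[1]
      }
    }
    for (ing in ans) {
      t <- t + stats::runif(1, 0.8, 2)
      ts <- c(ts, t); kind <- c(kind, "select"); target <- c(target, ing)
    }
    t <- t + 1
    ts <- c(ts, t); kind <- c(kind, "click"); target <- c(target, "confirm")
  }
  ev <- add_irrelevant(ts, kind, target,
                       stats::rpois(1, pr$sandwich_extra), max(ts) + 2)
  event_log("sandwich", pr$child_id, ev$t, ev$kind, ev$target,
            meta = list(presented = pres))
}

sim_monkey <- function(pr, cfg) {
  horizon <- 90
  sched <- monkey_visibility_schedule(cfg, total_time = horizon)
  t <- 0.5
  ts <- numeric(0)
  successes <- 0L
  attempts <- 0L
  while (successes < cfg$monkey_peels && attempts < 200L) {
    attempts <- attempts + 1L
    f <- stats::runif(1) < pr$inhibition_fail_rate
    tn <- place_swipe(t, f, sched, horizon)
    if (is.na(tn)) break
    ts <- c(ts, tn)
    t <- tn + stats::runif(1, 0.5, 1.5)
    if (!f) successes <- successes + 1L
  }
  n <- length(ts)
  ev <- add_irrelevant(ts, rep("click", n), rep("peel", n),
                       stats::rpois(1, pr$monkey_extra),
                       max(ts, 1) + 2)
  event_log("monkey", pr$child_id, ev$t, ev$kind, ev$target,
            meta = list(monkey_schedule = sched))
}

# next timestamp >= t inside a visible (fail) or hidden (success) phase
place_swipe <- function(t, visible, sched, horizon) {
  if (visible) {
    for (i in seq_len(nrow(sched))) {
      if (sched$end[i] >= t) {
        lo <- max(t, sched$start[i])
        return(stats::runif(1, lo, sched$end[i]))
      }
    }
    return(NA_real_)
  }
  # hidden = complement of the visible intervals on [0, horizon]
  bounds <- c(0, as.vector(t(as.matrix(sched[, c("start", "end")]))), horizon)
  starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  for (i in seq_along(starts)) {
    if (ends[i] > t && ends[i] > starts[i]) {
      lo <- max(t, starts[i])
      if (lo < ends[i]) return(stats::runif(1, lo, ends[i]))
    }
  }
  NA_real_
}

sim_magicland <- function(pr, cfg) {
  launches <- magicland_star_schedule(cfg)
  n <- length(launches)
  rt <- stats::rlnorm(n, pr$speed_mu, pr$speed_sigma)
  ts <- launches + rt
  ev <- add_irrelevant(ts, rep("click", n), paste0("star", seq_len(n)),
                       stats::rpois(1, n * pr$magicland_click_rate),
                       max(launches) + cfg$magicland_rise +
                         cfg$magicland_window)
  event_log("magicland", pr$child_id, ev$t, ev$kind, ev$target,
            meta = list(star_schedule = launches))
}

sim_rocket <- function(pr, cfg) {
  if (stats::runif(1) < pr$delay_commit_p)
    return(event_log("rocket", pr$child_id))
  # truncated-exponential quit time on [0, max_wait)
  u <- stats::runif(1)
  tau <- pr$delay_tolerance
  q <- -tau * log(1 - u * (1 - exp(-cfg$rocket_max_wait / tau)))
  event_log("rocket", pr$child_id, t = q, kind = "end_task")
}

sim_balloon <- function(pr, cfg) {
  t <- 0
  ts <- numeric(0); kind <- character(0)
  correct <- 0L
  w <- cfg$balloon_window
  while (correct < cfg$balloon_max_correct && t < cfg$balloon_timeout) {
    interval <- max(0.3, stats::rnorm(1, cfg$balloon_target, pr$timing_sd))
    ts <- c(ts, t, t + interval)
    kind <- c(kind, "start_hold", "stop_hold")
    if (interval >= w[1] && interval <= w[2]) correct <- correct + 1L
    t <- t + interval + stats::runif(1, 0.5, 1.5)
  }
  ev <- add_irrelevant(ts, kind, rep("", length(ts)),
                       stats::rpois(1, pr$balloon_extra), max(ts, 1))
  # irrelevant clicks must not break start/stop pairing: they are plain clicks
  event_log("balloon", pr$child_id, ev$t, ev$kind, ev$target)
}

#' Simulate, score and compile a full cohort
#'
#' Runs the whole generative pipeline: sample child profiles, simulate each
#' child's six event logs, score them with the engines, and compile the
#' outcome table. One global seed is fanned out to per-child substreams
#' (child `i` uses seed `seed + 104729 * i`, reduced modulo the integer
#' maximum), so enlarging the cohort does not perturb earlier children.
#'
#' @param params a [population_params()]; its `seed` drives profile
#'   sampling and the per-child substreams.
#' @param cfg a [game_config()].
#' @param keep_logs if TRUE, the per-child event logs are attached as
#'   attribute `"logs"` (a list named by child id).
#' @return Outcome data frame: one row per child, demographics plus the 14
#'   analysis variables.
#' @examples
#' params <- default_calibration(n_control = 5, n_adhd = 3, seed = 42)
#' tab <- simulate_cohort(params)
#' dim(tab)   # 8 x 19
#' @export
simulate_cohort <- function(params = default_calibration(),
                            cfg = game_config(), keep_logs = FALSE) {
  profiles <- sample_cohort(params)
  all_logs <- list()
  rows <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    pr <- profiles[i, ]
    child_seed <- (params$seed + 104729 * i) %% .Machine$integer.max
    logs <- simulate_child(pr, cfg, seed = child_seed)
    scores <- list(score_dressing(logs$dressing, cfg),
                   score_sandwich(logs$sandwich, cfg),
                   score_monkey(logs$monkey, cfg = cfg),
                   score_magic_land(logs$magicland, cfg = cfg),
                   score_rocket(logs$rocket, cfg),
                   score_balloon(logs$balloon, cfg))
    rows[[i]] <- compile_outcomes(scores,
                                  child_id = pr$child_id, group = pr$group,
                                  age = pr$age, sex = pr$sex,
                                  vocabulary_iq = pr$vocabulary_iq)
    if (keep_logs) all_logs[[pr$child_id]] <- logs
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_logs) attr(out, "logs") <- all_logs
  out
}
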