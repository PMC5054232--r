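cfg <- game_config()

test_that("dressing scores completeness and order against the dependency DAG", {
  ideal <- ideal_event_log("dressing", cfg)
  s <- score_dressing(ideal, cfg)
  expect_equal(s$scores$total, 2)
  expect_equal(s$n_clicks, 4)

  empty <- event_log("dressing")
  s0 <- score_dressing(empty, cfg)
  expect_equal(s0$scores$total, 0)
  expect_equal(s0$n_clicks, 0)

  # every permutation of the 4 garments, checked against a brute-force
  # edge checker: any order violating a dependency earns 1, not 2
  for (ord in permutations(cfg$dressing_garments)) {
    log <- event_log("dressing", t = seq_along(ord),
                     kind = rep("select", length(ord)), target = ord)
    sc <- score_dressing(log, cfg)
    expected <- 1 + as.integer(oracle_order_ok(ord, cfg$dressing_order))
    expect_equal(sc$scores$total, expected)
  }

  # incomplete dressing can never earn the order point
  partial <- event_log("dressing", t = 1:3, kind = rep("select", 3),
                       target = c("underwear", "shirt", "trousers"))
  expect_equal(score_dressing(partial, cfg)$scores$total, 0)
})

test_that("sandwich trials score only exact sequence reproduction", {
  ideal <- ideal_event_log("sandwich", cfg)
  s <- score_sandwich(ideal, cfg)
  expect_equal(s$scores$total, 5)
  expect_equal(s$n_clicks, 22)

  # first trial correct, rest answered with a wrong single item
  pres <- sandwich_presented(cfg)
  ts <- c(); kinds <- c(); targets <- c(); t <- 0
  for (i in seq_along(pres)) {
    ans <- if (i == 1) pres[[i]] else "wrong"
    for (a in ans) {
      t <- t + 1; ts <- c(ts, t); kinds <- c(kinds, "select")
      targets <- c(targets, a)
    }
    t <- t + 1; ts <- c(ts, t); kinds <- c(kinds, "click")
    targets <- c(targets, "confirm")
  }
  log <- event_log("sandwich", t = ts, kind = kinds, target = targets)
  expect_equal(score_sandwich(log, cfg)$scores$total, 1)

  # order must match exactly: (A, B, C) answered (A, C, B) scores 0
  log_acb <- event_log("sandwich", t = 1:4,
                       kind = c(rep("select", 3), "click"),
                       target = c("A", "C", "B", "confirm"))
  expect_equal(score_sandwich(log_acb, cfg,
                              presented = list(c("A", "B", "C")))$scores$total,
               0)
  log_abc <- event_log("sandwich", t = 1:4,
                       kind = c(rep("select", 3), "click"),
                       target = c("A", "B", "C", "confirm"))
  expect_equal(score_sandwich(log_abc, cfg,
                              presented = list(c("A", "B", "C")))$scores$total,
               1)

  # more trials than the schedule is a schema error
  six <- event_log("sandwich", t = 1:6, kind = rep("click", 6),
                   target = rep("confirm", 6))
  expect_error(score_sandwich(six, cfg), "more trials")
})

test_that("monkey failures are swipes inside visible intervals", {
  ideal <- ideal_event_log("monkey", cfg)
  s <- score_monkey(ideal, cfg = cfg)
  expect_equal(s$scores$failures, 0)
  expect_equal(s$n_clicks, 6)
  expect_true(s$complete)

  none <- event_log("monkey")
  s0 <- score_monkey(none, cfg = cfg)
  expect_equal(s0$scores$failures, 0)
  expect_false(s0$complete)

  sched <- data.frame(start = 2, end = 4)
  log <- make_log("monkey", t = c(1, 3, 5), target = rep("peel", 3))
  s1 <- score_monkey(log, schedule = sched, cfg = cfg)
  expect_equal(s1$scores$failures, 1)
  expect_equal(s1$scores$successes, 2)

  # closed interval: swipes exactly at the boundaries count as seen
  edge <- make_log("monkey", t = c(2, 4), target = rep("peel", 2))
  expect_equal(score_monkey(edge, schedule = sched,
                            cfg = cfg)$scores$failures, 2)
})

test_that("magic land credits clicks within the star window", {
  ideal <- ideal_event_log("magicland", cfg)
  s <- score_magic_land(ideal, cfg = cfg)
  expect_equal(s$scores$collected, 50)
  expect_equal(s$scores$mean_rt, 0.5)
  expect_equal(s$n_clicks, 50)

  empty <- event_log("magicland", meta = list(star_schedule = c(0, 5, 10)))
  s0 <- score_magic_land(empty, cfg = cfg)
  expect_equal(s0$scores$collected, 0)
  expect_true(is.na(s0$scores$mean_rt))

  # window arithmetic by hand with no rise animation: stars at 0, 5, 10
  # with a 2-s window; clicks at 1.0, 7.5 (late for star 2), 11.0
  flat <- game_config(magicland_rise = 0)
  log <- make_log("magicland", t = c(1.0, 7.5, 11.0),
                  meta = list(star_schedule = c(0, 5, 10)))
  s1 <- score_magic_land(log, cfg = flat)
  expect_equal(s1$scores$collected, 2)
  expect_equal(s1$scores$mean_rt, 1.0)
  expect_equal(s1$scores$missed, 1)

  # a single click is credited to at most one star
  overlap <- game_config(magicland_rise = 0, magicland_window = 10)
  log2 <- make_log("magicland", t = 6,
                   meta = list(star_schedule = c(0, 5, 10)))
  expect_equal(score_magic_land(log2, cfg = overlap)$scores$collected, 1)

  # explicit irrelevant clicks never collect but are counted
  log3 <- event_log("magicland", t = c(0.5, 0.6), kind = rep("click", 2),
                    target = c("none", "star1"),
                    meta = list(star_schedule = c(0, 5, 10)))
  s3 <- score_magic_land(log3, cfg = flat)
  expect_equal(s3$scores$collected, 1)
  expect_equal(s3$n_clicks, 2)
})

test_that("rocket wait is the end time capped at the maximum", {
  quit30 <- event_log("rocket", t = 30, kind = "end_task")
  s <- score_rocket(quit30, cfg)
  expect_equal(s$scores$choice, 0)
  expect_equal(s$scores$wait, 30)

  patient <- event_log("rocket")
  s1 <- score_rocket(patient, cfg)
  expect_equal(s1$scores$choice, 1)
  expect_equal(s1$scores$wait, 120)

  boundary <- event_log("rocket", t = 120, kind = "end_task")
  s2 <- score_rocket(boundary, cfg)
  expect_equal(s2$scores$choice, 1)
  expect_equal(s2$scores$wait, 120)
})

test_that("balloon intervals score on the closed window with the printed error formula", {
  holds <- function(intervals, gap = 2) {
    starts <- cumsum(c(0, head(intervals, -1) + gap))
    t <- as.vector(rbind(starts, starts + intervals))
    event_log("balloon", t = t,
              kind = rep(c("start_hold", "stop_hold"), length(intervals)))
  }
  s <- score_balloon(holds(c(9.5, 10.2, 12.0)), cfg)
  expect_equal(s$scores$correct, 2)
  expect_equal(s$scores$mean_abs_error, (0.5 + 0.2 + 2.0) / 3)

  s1 <- score_balloon(holds(c(10, 10, 10)), cfg)
  expect_equal(s1$scores$correct, 3)
  expect_equal(s1$scores$mean_abs_error, 0)
  expect_equal(s1$n_clicks, 6)

  # closed-interval boundaries both count as correct
  s2 <- score_balloon(holds(c(9.0, 11.0)), cfg)
  expect_equal(s2$scores$correct, 2)

  # error uses only the first three attempts; correct is capped at 3
  s3 <- score_balloon(holds(c(10, 10, 10, 10, 50)), cfg)
  expect_equal(s3$scores$correct, 3)
  expect_equal(s3$scores$mean_abs_error, 0)

  expect_error(score_balloon(event_log("balloon", t = 1,
                                       kind = "stop_hold"), cfg),
               "malformed")
  expect_true(is.na(score_balloon(event_log("balloon"),
                                  cfg)$scores$mean_abs_error))
})

test_that("compile_outcomes produces the 14 analysis variables in fixed order", {
  scores <- lapply(game_ids(), function(g)
    score_log(ideal_event_log(g, cfg), cfg))
  row <- compile_outcomes(scores, child_id = "x", group = "control",
                          age = 7, sex = "f")
  expect_equal(names(row)[6:19], outcome_variables()$variable)
  expect_equal(row$dressing_total, 2)
  expect_equal(row$sandwich_total, 5)
  expect_equal(row$monkey_failures, 0)
  expect_equal(row$magicland_stars, 50)
  expect_equal(row$rocket_choice, 1)
  expect_equal(row$balloon_correct, 3)

  # empty logs: minimum engine scores, zero clicks, missing reaction time
  empties <- lapply(game_ids(), function(g) score_log(event_log(g), cfg))
  r0 <- compile_outcomes(empties)
  expect_equal(r0$dressing_total, 0)
  expect_equal(r0$magicland_stars, 0)
  expect_true(is.na(r0$magicland_mean_rt))
  expect_equal(r0$dressing_clicks + r0$sandwich_clicks + r0$monkey_clicks +
                 r0$magicland_clicks + r0$balloon_clicks, 0)
  # a log with no end_task means the full wait and the large reward
  expect_equal(r0$rocket_wait, 120)

  expect_error(compile_outcomes(scores[-1]), "missing task score")
  expect_error(compile_outcomes(c(scores, scores[1])), "duplicate")
})

test_that("scoring is deterministic and respects outcome bounds on simulated logs", {
  params <- default_calibration(n_control = 12, n_adhd = 12, seed = 303)
  tab <- simulate_cohort(params, cfg, keep_logs = TRUE)
  expect_true(all(tab$dressing_total >= 0 & tab$dressing_total <= 2))
  expect_true(all(tab$sandwich_total >= 0 & tab$sandwich_total <= 5))
  expect_true(all(tab$balloon_correct >= 0 & tab$balloon_correct <= 3))
  expect_true(all(tab$magicland_stars >= 0 & tab$magicland_stars <= 50))
  expect_true(all(tab$rocket_wait >= 0 & tab$rocket_wait <= 120))
  expect_true(all(tab$monkey_failures >= 0))
  expect_true(all(tab$rocket_choice %in% c(0, 1)))
  expect_true(all((tab$rocket_choice == 1) == (tab$rocket_wait == 120)))

  logs <- attr(tab, "logs")
  for (child in names(logs)[1:4]) {
    for (g in game_ids()) {
      log <- logs[[child]][[g]]
      s1 <- score_log(log, cfg)
      s2 <- score_log(log, cfg)
      expect_identical(s1, s2)
      # click accounting: scorer count equals the raw event count
      expect_equal(s1$n_clicks,
                   sum(log$events$kind %in%
                         c("click", "select", "start_hold", "stop_hold")))
      if (g == "magicland") {
        expect_equal(s1$scores$collected + s1$scores$missed, 50)
      }
    }
  }
})
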