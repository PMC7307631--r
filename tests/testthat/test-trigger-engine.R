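make_pose <- function(y_left, y_right = 100, conf = 1) {
  tibble::tibble(label = c("L1", "L2", "L3", "L4", "R1", "R2", "R3", "R4"),
                 x = 1:8,
                 y = c(rep(y_left, 4), rep(y_right, 4)),
                 confidence = conf)
}

test_that("paw displacement is the absolute change in mean paw y", {
  d <- paw_displacement(make_pose(100), make_pose(90), second_frame_time = 20)
  expect_equal(d$dy_left, 10)
  expect_equal(d$dy_right, 0)

  # identical poses -> zero displacement
  d0 <- paw_displacement(make_pose(100), make_pose(100))
  expect_equal(c(d0$dy_left, d0$dy_right), c(0, 0))

  # sign symmetry: up and down 7 px moves are equivalent
  up <- paw_displacement(make_pose(100), make_pose(93))
  down <- paw_displacement(make_pose(100), make_pose(107))
  expect_equal(up$dy_left, 7)
  expect_equal(down$dy_left, 7)

  # confidence aggregation: mean vs min over the second frame
  p2 <- make_pose(95)
  p2$confidence <- c(1, 1, 1, 1, 1, 1, 1, 0.2)
  dm <- paw_displacement(make_pose(100), p2, confidence_aggregate = "mean")
  dmin <- paw_displacement(make_pose(100), p2, confidence_aggregate = "min")
  expect_equal(dm$confidence, 0.9)
  expect_equal(dmin$confidence, 0.2)
})

test_that("the criterion gate truth table matches the documented rules", {
  cfg <- criterion_config()
  st <- engine_state()
  dd <- function(dy_left, dy_right = 2, conf = 0.9, t = 1000,
                 state = st) {
    evaluate_criterion(list(dy_left = dy_left, dy_right = dy_right,
                            confidence = conf, second_frame_time = t),
                       cfg, state)
  }
  # canonical pass
  expect_identical(dd(7)$decision, "TRIGGER")
  # lower bound inclusive at 5, upper inclusive at 100
  expect_identical(dd(5)$decision, "TRIGGER")
  expect_identical(dd(100)$decision, "TRIGGER")
  expect_identical(dd(4.99)$reason, "below_min")
  expect_identical(dd(150)$reason, "above_max")
  expect_identical(dd(100.01)$reason, "above_max")
  # contralateral veto: 10 px allowed, above 10 vetoes
  expect_identical(dd(7, dy_right = 10)$decision, "TRIGGER")
  expect_identical(dd(7, dy_right = 10.01)$reason, "contralateral")
  expect_identical(dd(7, dy_right = 12)$reason, "contralateral")
  # confidence strictly greater than 0.20
  expect_identical(dd(7, conf = 0.15)$reason, "low_confidence")
  expect_identical(dd(7, conf = 0.20)$reason, "low_confidence")
  expect_identical(dd(7, conf = 0.2001)$decision, "TRIGGER")
})

test_that("the refractory period suppresses and re-arms strictly after 300 ms", {
  cfg <- criterion_config()
  st <- engine_state()
  pass <- function(t) list(dy_left = 7, dy_right = 2, confidence = 0.9,
                           second_frame_time = t)
  # no prior trigger: any passing pair allowed
  d1 <- evaluate_criterion(pass(1000), cfg, st)
  expect_identical(d1$decision, "TRIGGER")
  st <- update_refractory(st, d1, 1000)
  expect_equal(st$last_trigger_time, 1000)
  expect_identical(st$trigger_count, 1L)

  # within the period: suppressed regardless of movement size
  expect_identical(evaluate_criterion(pass(1250), cfg, st)$reason,
                   "refractory")
  big <- list(dy_left = 90, dy_right = 0, confidence = 1,
              second_frame_time = 1299)
  expect_identical(evaluate_criterion(big, cfg, st)$reason, "refractory")
  # boundary is strict: exactly 300 ms elapsed still suppressed, 301 allowed
  expect_identical(evaluate_criterion(pass(1300), cfg, st)$reason,
                   "refractory")
  expect_identical(evaluate_criterion(pass(1301), cfg, st)$decision,
                   "TRIGGER")
  # a suppressed passing pair must not reset the clock
  st2 <- update_refractory(st, evaluate_criterion(pass(1250), cfg, st), 1250)
  expect_equal(st2$last_trigger_time, 1000)
})

test_that("the offline oracle scans scripted sessions correctly", {
  # 3 left reaches spaced >= 1 s -> 3 events
  sess <- generate_pose_trace(reach_script(c(1, 2.5, 4), duration = 5.5))
  ev <- offline_oracle(sess$trace)
  expect_identical(nrow(ev), 3L)

  # grooming-like co-movement: both paws above their thresholds on every
  # pair -> the contralateral veto suppresses all of it
  n <- 200
  yl <- 100 + rep(c(0, 10), n / 2)   # dy_left = 10 on every pair
  yr <- 100 + rep(c(0, 12), n / 2)   # dy_right = 12 > 10 on every pair
  expect_identical(nrow(offline_oracle(toy_trace(yl, yr))), 0L)
  # the same left movement alone triggers at the refractory-limited rate
  expect_gt(nrow(offline_oracle(toy_trace(yl))), 0L)

  # empty trace -> empty event list
  expect_identical(nrow(offline_oracle(toy_trace(numeric(0)))), 0L)
})

test_that("online engine equals the oracle across randomized sessions", {
  for (s in 1:25) {
    sc <- random_session_script(2000 + s)
    sess <- generate_pose_trace(sc)
    onl <- run_engine(open_replay_source(sess$trace))
    orc <- offline_oracle(sess$trace)
    expect_identical(onl$events$pair_index, orc$pair_index)
    expect_identical(onl$events$second_frame, orc$second_frame)
  }
})

test_that("selectivity: right-only sessions never trigger, left-only match the oracle", {
  right <- generate_pose_trace(
    reach_script(c(1, 2, 3), paw = "right", duration = 4.5))
  expect_identical(nrow(run_engine(open_replay_source(right$trace))$events),
                   0L)
  left <- generate_pose_trace(
    reach_script(c(1, 2, 3), paw = "left", duration = 4.5))
  onl <- run_engine(open_replay_source(left$trace))
  expect_identical(nrow(onl$events), nrow(offline_oracle(left$trace)))
  expect_gt(nrow(onl$events), 0L)
})

test_that("trigger counts respond monotonically to stricter thresholds", {
  sess <- generate_pose_trace(random_session_script(77))
  n_for <- function(min_left = 5, refractory = 300) {
    nrow(offline_oracle(sess$trace,
                        criterion_config(min_left = min_left,
                                         refractory = refractory)))
  }
  base <- n_for()
  for (ml in c(8, 12, 20)) expect_lte(n_for(min_left = ml), base)
  for (rf in c(500, 900)) expect_lte(n_for(refractory = rf), base)
})

test_that("successive triggers are separated by more than the refractory period", {
  for (s in c(5, 17)) {
    sess <- generate_pose_trace(random_session_script(s))
    ev <- run_engine(open_replay_source(sess$trace))$events
    if (nrow(ev) > 1)
      expect_true(all(diff(ev$frame_time_ms) > 300))
  }
})

test_that("criterion configuration enforces its invariants", {
  expect_error(criterion_config(min_left = 0),
               class = "pawtrigger_config_error")
  expect_error(criterion_config(min_left = 20, max_left = 10),
               class = "pawtrigger_config_error")
  expect_error(criterion_config(confidence_min = 1.5),
               class = "pawtrigger_config_error")
  expect_error(criterion_config(refractory = -1),
               class = "pawtrigger_config_error")
  expect_error(criterion_config(max_right = 0),
               class = "pawtrigger_config_error")
})
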