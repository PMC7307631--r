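test_that("time-stamp latency is dispatch minus movement-frame time", {
  ev <- tibble::tibble(frame_time_ms = c(1000, 2000),
                       dispatch_time_ms = c(1040, 2030))
  lat <- timestamp_latency(ev)
  expect_equal(lat$latencies, c(40, 30))
  expect_equal(lat$mean, 35)

  # constant injected processing delay -> mean = delay, sd = 0 (plus the
  # sub-ms device leg)
  sess <- generate_pose_trace(reach_script(c(2, 3, 4, 5), duration = 6))
  cfg <- session_config(buffer_duration = 1, post_buffer_wait = 100,
                        recording_duration = 5, input_frame_rate = 50,
                        processing_delay_ms = 30)
  rec <- run_trial(sess$trace, cfg, device = mock_device(latency_ms = 0))
  lat2 <- timestamp_latency(rec)
  expect_equal(lat2$mean, 30)
  expect_equal(lat2$sd, 0)

  # zero-event trial -> empty signal
  quiet <- run_trial(generate_pose_trace(quiet_script(duration = 6))$trace,
                     cfg)
  expect_true(timestamp_latency(quiet)$empty)
})

test_that("flash detection crosses at 3 SD, skips early frames, and re-arms", {
  # alternating 49/51 baseline (mean 50, sd ~1): flash of 80 at 900-913
  y <- rep(c(49, 51), 500)
  y[900:913] <- 80
  tr <- led_trace(y, skip_frames = 800)
  expect_identical(detect_flashes(tr), 900L)

  # a flash wholly inside the skip window is never reported
  y2 <- rep(c(49, 51), 500)
  y2[300:313] <- 80
  expect_length(detect_flashes(led_trace(y2, skip_frames = 800)), 0L)

  # flat trace -> no onsets (epsilon SD floor, with a warning)
  expect_warning(tr3 <- led_trace(rep(50, 1000), skip_frames = 800),
                 "zero-variance")
  expect_length(detect_flashes(tr3), 0L)

  # two flashes separated by a return below threshold -> two onsets
  y4 <- rep(c(49, 51), 2500)
  y4[850:860] <- 80
  y4[880:890] <- 80
  expect_identical(detect_flashes(led_trace(y4, skip_frames = 800)),
                   c(850L, 880L))

  # adding a constant to the whole trace changes nothing
  expect_identical(detect_flashes(led_trace(y + 17.5, skip_frames = 800)),
                   detect_flashes(tr))

  expect_error(led_trace(rep(1, 100), skip_frames = 800),
               class = "pawtrigger_input_error")
})

test_that("ground-truth latency recovers a scripted lamp delay", {
  # events at known frame times; LED onsets rendered a fixed delay later
  t_ms <- (0:999) * 10  # 100 Hz
  events <- tibble::tibble(frame_time_ms = c(2000, 4000, 6000))
  onset_frames <- c(205L, 405L, 605L)  # 40 ms later (1-based frames)
  lat <- ground_truth_latency(onset_frames, events, t_ms)
  expect_equal(lat$latencies, c(40, 40, 40))
  expect_identical(lat$method, "ground_truth")

  # event with no onset inside the window is flagged unmatched
  lat2 <- ground_truth_latency(c(205L), tibble::tibble(
    frame_time_ms = c(2000, 6000)), t_ms)
  expect_identical(lat2$unmatched, 2L)
  expect_equal(lat2$latencies, 40)

  # more onsets than events is an alignment error
  expect_error(ground_truth_latency(c(204L, 404L),
                                    tibble::tibble(frame_time_ms = 2000),
                                    t_ms),
               class = "pawtrigger_input_error")
})

test_that("paired comparison of the two latency methods matches closed form", {
  # differences [1,2,2,1]: t = mean/(sd/sqrt(n)) = 1.5/(0.5774/2) = 5.196
  paired <- tibble::tibble(timestamp = c(10, 20, 30, 40),
                           ground_truth = c(11, 22, 32, 41))
  res <- compare_latency_methods(paired)
  expect_equal(res$t, 5.196, tolerance = 1e-3)
  expect_identical(res$df, 3)
  expect_equal(res$mean_difference, 1.5)

  # identical pairs -> zero-variance case, t reported as 0
  same <- tibble::tibble(timestamp = c(10, 20), ground_truth = c(10, 20))
  res0 <- compare_latency_methods(same)
  expect_true(res0$zero_variance)
  expect_equal(res0$t, 0)

  expect_error(compare_latency_methods(tibble::tibble(
    timestamp = 1, ground_truth = 2)), class = "pawtrigger_input_error")
})

test_that("the paired test holds its nominal size under a true zero offset", {
  # Monte-Carlo calibration: 5 trials per experiment, no method difference
  reject <- withr::with_seed(404, {
    vapply(1:600, function(i) {
      ts <- rnorm(5, 30, 5)
      gt <- ts + rnorm(5, 0, 3)
      compare_latency_methods(tibble::tibble(timestamp = ts,
                                             ground_truth = gt))$p < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(reject) - 0.05), 0.03)
})

test_that("sampling-adequacy and spatial calibration utilities are exact", {
  expect_equal(nyquist_limit(65.59), 32.80)
  expect_equal(nyquist_limit(0), 0)
  expect_equal(nyquist_limit(90), 45)
  expect_error(nyquist_limit(-1), class = "pawtrigger_input_error")

  expect_equal(px_to_mm(256, 44 / 256), 44)
  expect_equal(px_to_mm(0, 0.2), 0)
  expect_equal(px_to_mm(5, 44 / 256), 0.859, tolerance = 1e-3)
  expect_error(px_to_mm(5, 0), class = "pawtrigger_input_error")
})

test_that("baseline guard windows keep flashes out of the background statistics", {
  withr::with_seed(7, {
    n <- 1600
    y <- 50 + runif(n, -2, 2)  # bounded background fluctuation
    onsets <- c(900, 1100, 1300)
    for (o in onsets) y[o:(o + 13)] <- y[o:(o + 13)] + 30
    t_ms <- (seq_len(n) - 1) * 10
    tr <- led_trace(y, t_ms = t_ms, skip_frames = 800,
                    guard_events = t_ms[onsets], guard_ms = 300)
    # guarded baseline stays near the clean statistics
    expect_lt(abs(tr$baseline_mean - 50), 0.5)
    expect_lt(tr$baseline_sd, 2)
    expect_identical(detect_flashes(tr), as.integer(onsets))
  })
})
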