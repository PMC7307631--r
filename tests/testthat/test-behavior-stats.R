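collection <- function(...) structure(list(...), class = "trial_collection")

test_that("trigger counting tabulates trials and matches the oracle", {
  sess <- generate_pose_trace(reach_script(c(1, 2.5, 4), duration = 5.5))
  cfg <- session_config(buffer_duration = 0, post_buffer_wait = 0,
                        recording_duration = 5.5, input_frame_rate = 50)
  rec <- run_trial(sess$trace, cfg, mouse = "m1", day = 1L)
  counts <- count_triggers(collection(rec))
  expect_identical(counts$n_triggers, 3L)
  expect_identical(counts$n_triggers, nrow(offline_oracle(sess$trace)))

  # per-day mean is the arithmetic mean over that day's trials
  rec2 <- run_trial(generate_pose_trace(
    reach_script(c(1, 3), duration = 5.5))$trace, cfg, mouse = "m1",
    day = 1L, trial = 2L)
  cm <- mean_trigger_counts(count_triggers(collection(rec, rec2)))
  expect_equal(cm$mean_triggers, 2.5)
})

test_that("post-trigger contralateral movements are counted on the next pair", {
  # left-only reaches -> zero contralateral follow-ups
  sess <- generate_pose_trace(reach_script(c(1, 2, 3), duration = 4.5))
  ev <- offline_oracle(sess$trace)
  res <- count_post_trigger_contralateral(sess$trace, ev)
  expect_identical(res$n_post_trigger_contralateral, 0L)

  # hand-built: a 15 px right jump on the pair after each trigger
  y_left <- rep(100, 40)
  y_left[c(10, 24)] <- 110          # pairs (9,10) and (23,24) trigger
  y_right <- rep(100, 40)
  y_right[c(12, 26)] <- 115         # next pairs (11,12), (25,26) jump right
  tr <- toy_trace(y_left, y_right, t_ms = (0:39) * 400)
  ev2 <- offline_oracle(tr)
  expect_identical(nrow(ev2), 2L)
  res2 <- count_post_trigger_contralateral(tr, ev2)
  expect_identical(res2$n_post_trigger_contralateral, 2L)

  # an infinite threshold can never count anything
  res3 <- count_post_trigger_contralateral(tr, ev2, threshold = Inf)
  expect_identical(res3$n_post_trigger_contralateral, 0L)

  # a trigger on the final pair is skipped with a note
  y4 <- rep(100, 10); y4[10] <- 110
  tr4 <- toy_trace(y4, t_ms = (0:9) * 400)
  ev4 <- offline_oracle(tr4)
  res4 <- count_post_trigger_contralateral(tr4, ev4)
  expect_identical(res4$n_skipped, 1L)
})

test_that("per-digit movement counts follow the shared pairing conventions", {
  # a coherent 20 px reach increments all four left digits equally
  sess <- generate_pose_trace(reach_script(c(1, 2), duration = 3,
                                           frame_rate = 40))
  dc <- count_digit_movements(sess$trace, "left")
  expect_identical(length(unique(dc$n_moves)), 1L)
  expect_gt(dc$n_moves[1], 0)

  # single-digit jitter only moves that digit's count
  tr <- toy_trace(rep(100, 20), t_ms = (0:19) * 20)
  tr$L2_y[10] <- 120
  dc2 <- count_digit_movements(tr, "left")
  expect_identical(dc2$n_moves[dc2$digit == "L2"], 1L)
  expect_identical(sum(dc2$n_moves), 1L)

  # zero-movement trace -> all zeros; right paw uses a strict > rule
  dc3 <- count_digit_movements(toy_trace(rep(100, 20)), "right")
  expect_true(all(dc3$n_moves == 0L))
  tr4 <- toy_trace(rep(100, 4), rep(c(100, 110), 2))
  expect_true(all(count_digit_movements(tr4, "right")$n_moves == 0L))
  tr5 <- toy_trace(rep(100, 4), rep(c(100, 110.5), 2))
  expect_true(all(count_digit_movements(tr5, "right")$n_moves == 2L))
})

test_that("paired t with Bonferroni matches the closed form and caps at 1", {
  counts <- tibble::tibble(
    mouse = rep(c("a", "b", "c", "d"), each = 2),
    day = rep(c(1L, 2L), 4),
    mode = "training",
    trial = 1L,
    n_triggers = c(10, 11, 10, 12, 10, 12, 10, 11))
  cmp <- tibble::tibble(day_a = 2L, mode_a = "training",
                        day_b = 1L, mode_b = "training")
  res <- paired_t_bonferroni(counts, cmp)
  expect_equal(res$t, 5.196, tolerance = 1e-3)
  expect_identical(res$df, 3)
  # family-of-4 correction: p_adj = min(1, 4p)
  res4 <- paired_t_bonferroni(counts, cmp, family_size = 4)
  expect_equal(res4$p_adj, min(1, res$p * 4))
  res_huge <- paired_t_bonferroni(counts, cmp, family_size = 1e6)
  expect_equal(res_huge$p_adj, 1)

  # identical cells -> zero variance, flagged not significant
  counts0 <- counts
  counts0$n_triggers <- 5
  res0 <- paired_t_bonferroni(counts0, cmp)
  expect_true(res0$zero_variance)
  expect_false(res0$significant)

  # missing mouse on one side names the pairing error
  expect_error(paired_t_bonferroni(counts[-2, ], cmp),
               class = "pawtrigger_input_error")
})

test_that("digit ANOVA is calibrated and detects a shifted digit", {
  # two-digit case: F equals the square of the two-sample t statistic
  withr::with_seed(5, {
    d2 <- tibble::tibble(
      mouse = "m", day = 1L, mode = "training",
      trial = rep(1:10, 2),
      digit = rep(c("L1", "L2"), each = 10),
      n_moves = c(rnorm(10, 20, 3), rnorm(10, 24, 3)))
  })
  a <- anova_digits(d2)
  tt <- t.test(n_moves ~ digit, data = d2, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-8)

  # a strongly shifted digit is flagged
  withr::with_seed(6, {
    d4 <- tidyr::expand_grid(trial = 1:8, digit = c("L1", "L2", "L3", "L4"))
    d4$mouse <- "m"; d4$day <- 1L; d4$mode <- "training"
    d4$n_moves <- rnorm(nrow(d4), 20, 2) + ifelse(d4$digit == "L3", 15, 0)
  })
  a4 <- anova_digits(d4)
  expect_lt(a4$p, 1e-3)

  # null calibration: rejection rate near alpha
  withr::with_seed(7, {
    rej <- vapply(1:300, function(i) {
      dd <- tidyr::expand_grid(trial = 1:6, digit = c("L1", "L2", "L3", "L4"))
      dd$mouse <- "m"; dd$day <- 1L; dd$mode <- "training"
      dd$n_moves <- rnorm(nrow(dd), 20, 3)
      anova_digits(dd)$p < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(rej) - 0.05), 0.04)

  # an empty stratum is skipped with a note
  empty <- tibble::tibble(mouse = "m", day = 1L, mode = "training",
                          trial = 1L, digit = "L1", n_moves = 3L)
  expect_match(anova_digits(empty)$note, "skipped")
})

test_that("bootstrap estimation is exact on degenerate input and seeded", {
  # all pairwise differences equal c -> point interval at c
  pairs <- tibble::tibble(a = c(12, 15, 9), b = c(2, 5, -1))
  est <- bootstrap_mean_difference(pairs, n_resamples = 500, seed = 1)
  expect_equal(est$mean_difference, 10)
  expect_equal(c(est$ci_low, est$ci_high), c(10, 10))

  # determinism under the seed
  withr::with_seed(3, {
    d <- tibble::tibble(a = rnorm(7, 12, 2), b = rnorm(7, 5, 2))
  })
  e1 <- bootstrap_mean_difference(d, n_resamples = 1000, seed = 11)
  e2 <- bootstrap_mean_difference(d, n_resamples = 1000, seed = 11)
  expect_identical(tidy(e1), tidy(e2))
  e3 <- bootstrap_mean_difference(d, n_resamples = 1000, seed = 12)
  expect_false(identical(e1$ci_low, e3$ci_low))

  # invariant: ci_low <= estimate <= ci_high
  expect_true(e1$ci_low <= e1$mean_difference &&
                e1$mean_difference <= e1$ci_high)

  expect_error(bootstrap_mean_difference(d, n_resamples = 50, seed = 1),
               class = "pawtrigger_config_error")
  expect_error(bootstrap_mean_difference(tibble::tibble(a = 1, b = 2),
                                         n_resamples = 500, seed = 1),
               class = "pawtrigger_input_error")
})

test_that("percentile bootstrap agrees with an independent implementation", {
  withr::with_seed(13, {
    d <- tibble::tibble(a = rnorm(9, 10, 3), b = rnorm(9, 6, 3))
  })
  est <- bootstrap_mean_difference(d, n_resamples = 4000, seed = 2,
                                   method = "percentile")
  bt <- boot::boot(d$a - d$b, function(x, i) mean(x[i]), R = 4000)
  ci <- boot::boot.ci(bt, type = "perc")$percent[4:5]
  expect_equal(est$ci_low, ci[1], tolerance = 0.15)
  expect_equal(est$ci_high, ci[2], tolerance = 0.15)

  # and the BCa flavour against boot's BCa on the same data
  estb <- bootstrap_mean_difference(d, n_resamples = 4000, seed = 2,
                                    method = "bca")
  cib <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_equal(estb$ci_low, cib[1], tolerance = 0.15)
  expect_equal(estb$ci_high, cib[2], tolerance = 0.15)
})

test_that("a large paired effect yields intervals that exclude zero", {
  withr::with_seed(21, {
    excl <- vapply(1:40, function(i) {
      d <- tibble::tibble(a = rnorm(7, 10, 1), b = rnorm(7, 0, 1))
      est <- bootstrap_mean_difference(d, n_resamples = 600, seed = 1000 + i)
      est$ci_low > 0
    }, logical(1))
  })
  expect_true(all(excl))
})

test_that("estimation tables cover the standard day-wise contrasts", {
  counts <- tidyr::expand_grid(mouse = paste0("m", 1:6), day = 1:3,
                               mode = c("baseline", "training"), trial = 1:2)
  withr::with_seed(8, {
    counts$n_triggers <- rpois(nrow(counts),
                               ifelse(counts$mode == "training",
                                      8 + 4 * (counts$day - 1), 6))
  })
  tb <- estimation_by_day(counts, "training_vs_baseline",
                          n_resamples = 500, seed = 5)
  expect_identical(tb$day, 1:3)
  expect_true(all(tb$excludes_zero[2:3]))
  td <- estimation_by_day(counts, "training_vs_day1",
                          n_resamples = 500, seed = 5)
  expect_identical(td$day, 2:3)
  expect_true(td$excludes_zero[2])
})
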