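#' Run one trial through the full streaming pipeline
#'
#' Orchestrates a complete trial: the source is consumed pair by pair, the
#' buffer period is analyzed but not persisted, every post-buffer pair is
#' evaluated against the criterion, triggers are dispatched through the
#' feedback device (red LED always; water only on training trials), and the
#' trial-type cue is set. Returns a self-contained trial record.
#'
#' @param trace Pose trace tibble for the trial (placeholder rows included).
#' @param config A [session_config()].
#' @param criterion A [criterion_config()].
#' @param mode `"training"` or `"baseline"`.
#' @param backend Pose backend function (default [replay_pose()]).
#' @param frames Optional `frame_stack` to attach images to the source.
#' @param device A [mock_device()]; a fresh one is created by default.
#' @param persistence_delay_ms Injected labeled-frame persistence cost, ms;
#'   persistence is asynchronous and must not move dispatch time stamps.
#' @param mouse,day,trial Identifiers stored in the record.
#' @return A `trial_record` with `events`, `decisions`, `feedback`,
#'   `frame_stats`, `throughput`, the config snapshots, identifiers and the
#'   cue state.
#' @export
#' @examples
#' sc <- motion_script(duration = 14, frame_rate = 60, drop_probability = 0.1,
#'                     reach_events = reach_schedule(c(11, 12, 13)), seed = 3)
#' sess <- generate_pose_trace(sc)
#' rec <- run_trial(sess$trace, session_config(buffer_duration = 10,
#'                  recording_duration = 4, input_frame_rate = 60))
#' nrow(rec$events)
run_trial <- function(trace, config = session_config(),
                      criterion = criterion_config(),
                      mode = c("training", "baseline"),
                      backend = replay_pose, frames = NULL,
                      device = mock_device(), persistence_delay_ms = 0,
                      mouse = "m1", day = 1L, trial = 1L) {
  mode <- match.arg(mode)
  total_ms <- (config$buffer_duration + config$recording_duration) * 1000
  if (max(trace$t_ms) < config$buffer_duration * 1000)
    rlang::abort("source exhausted before the buffer period ended",
                 class = "pawtrigger_truncated_trial")
  truncated <- max(trace$t_ms) < total_ms - 1000

  src <- open_replay_source(trace, frames = frames)
  cue_on <- set_cue(device, mode, t_start = 0, t_end = total_ms)
  res <- run_engine(src, criterion, backend = backend, device = device,
                    mode = mode, persist_start_ms = persist_start_ms(config),
                    processing_delay_ms = config$processing_delay_ms,
                    persistence_delay_ms = persistence_delay_ms)

  ledger <- drop_ledger(trace)
  rec_frames <- sum(!trace$dropped &
                    trace$t_ms >= config$buffer_duration * 1000)
  stats <- tibble(
    emitted = ledger$emitted,
    processed = ledger$processed,
    dropped = ledger$dropped,
    mean_output_rate_hz = rec_frames / config$recording_duration,
    truncated = truncated
  )
  structure(list(
    mouse = mouse, day = as.integer(day), trial = as.integer(trial),
    mode = mode, cue_on = cue_on,
    events = res$events, decisions = res$decisions, feedback = res$feedback,
    frame_stats = stats, throughput = ledger$throughput,
    device_timeline = device_timeline(device),
    config = config, criterion = criterion
  ), class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s day %d trial %d (%s): %d trigger(s), %d/%d frames processed\n",
              x$mouse, x$day, x$trial, x$mode, nrow(x$events),
              x$frame_stats$processed, x$frame_stats$emitted))
  invisible(x)
}

#' Run a scheduled multi-trial experiment
#'
#' Executes a schedule of trials (typically alternating baseline and
#' training within each day, across days and mice) and collects the trial
#' records for the behavior-statistics pipeline.
#'
#' @param schedule Tibble with columns `mouse`, `day`, `trial`, `mode`, and
#'   a list-column `trace` holding each trial's pose trace.
#' @param config A [session_config()] shared by all trials.
#' @param criterion A [criterion_config()] shared by all trials.
#' @return A list of `trial_record`s (class `trial_collection`).
#' @export
run_experiment <- function(schedule, config = session_config(),
                           criterion = criterion_config()) {
  need <- c("mouse", "day", "trial", "mode", "trace")
  if (!all(need %in% names(schedule)))
    abort_input("schedule needs columns %s", paste(need, collapse = ", "))
  key <- paste(schedule$mouse, schedule$day, schedule$trial)
  if (anyDuplicated(key))
    abort_input("duplicate (mouse, day, trial) in schedule: %s",
                key[duplicated(key)][1])
  records <- purrr::pmap(schedule, function(mouse, day, trial, mode, trace, ...) {
    run_trial(trace, config, criterion, mode = mode,
              mouse = mouse, day = day, trial = trial)
  })
  structure(records, class = "trial_collection")
}

#' @export
print.trial_collection <- function(x, ...) {
  cat(sprintf("<trial_collection> %d trial(s)\n", length(x)))
  invisible(x)
}

#' Simulate a multi-day reinforcement experiment
#'
#' Generates the synthetic analogue of the 5-day alternating
#' baseline/training protocol: for every row of `design` a motion script is
#' drawn with the requested left-reach rate (reaches placed on a jittered
#' grid so they stay resolvable at the refractory period), the trial is run
#' through the full pipeline, and the records are returned for analysis.
#'
#' @param design Tibble with columns `mouse`, `day`, `mode`, `n_trials`, and
#'   `reach_rate` (left reaches per trial, scripted during the recording
#'   window).
#' @param duration,frame_rate Trial length (s) and frame rate (Hz).
#' @param config A [session_config()] (its buffer should fit `duration`).
#' @param criterion A [criterion_config()].
#' @param amplitude Reach amplitude, px.
#' @param rate_sd Mouse-by-trial SD of the realized reach count.
#' @param drop_probability,baseline_jitter_sd Passed to [motion_script()].
#' @param seed Master seed; per-trial seeds are derived deterministically.
#' @return A `trial_collection`.
#' @export
simulate_experiment <- function(design,
                                duration = 16, frame_rate = 60,
                                config = session_config(
                                  buffer_duration = 2, post_buffer_wait = 100,
                                  recording_duration = duration - 2,
                                  input_frame_rate = frame_rate),
                                criterion = criterion_config(),
                                amplitude = 20, rate_sd = 1,
                                drop_probability = 0.05,
                                baseline_jitter_sd = 0.5,
                                seed = 1L) {
  need <- c("mouse", "day", "mode", "n_trials", "reach_rate")
  if (!all(need %in% names(design)))
    abort_input("design needs columns %s", paste(need, collapse = ", "))
  rows <- tidyr::uncount(design, weights = .data$n_trials, .id = "trial")
  # interleave modes within each (mouse, day): baseline/training alternate
  rows <- rows |>
    group_by(.data$mouse, .data$day) |>
    arrange(.data$trial, .data$mode, .by_group = TRUE) |>
    mutate(trial = seq_len(dplyr::n())) |>
    ungroup()
  rows$trial <- as.integer(rows$trial)

  schedule <- withr::with_seed(seed, {
    rows$trace <- purrr::pmap(rows, function(mouse, day, mode, reach_rate,
                                             trial, ...) {
      n_reach <- max(0L, round(rnorm(1, reach_rate, rate_sd)))
      rec_start <- config$buffer_duration + 0.5
      rec_len <- duration - rec_start - 0.5
      onsets <- if (n_reach > 0) {
        grid <- rec_start + rec_len * (seq_len(n_reach) - 0.5) / n_reach
        jit <- runif(n_reach, -0.4, 0.4) * rec_len / max(n_reach, 1)
        sort(pmin(pmax(grid + jit, rec_start), duration - 0.3))
      } else numeric()
      sc <- motion_script(
        duration = duration, frame_rate = frame_rate,
        reach_events = reach_schedule(onsets, amplitude = amplitude),
        drop_probability = drop_probability,
        baseline_jitter_sd = baseline_jitter_sd,
        seed = sample.int(.Machine$integer.max, 1))
      generate_pose_trace(sc)$trace
    })
    rows
  })
  run_experiment(schedule, config, criterion)
}

#' Quality-control filter for trial records
#'
#' Declarative exclusion rules applied before any summary statistics:
#' trials whose mean time-stamp latency exceeds `max_mean_latency_ms`
#' (malfunctioning runs) and trials with no above-criterion events are
#' dropped; mice not present on all `required_days` can be excluded
#' entirely.
#'
#' @param records A `trial_collection`.
#' @param max_mean_latency_ms Latency exclusion bound, ms.
#' @param drop_zero_event Drop trials with zero triggers?
#' @param required_days If non-`NULL`, keep only mice with records on every
#'   one of these days.
#' @return The filtered `trial_collection`; excluded trials are reported via
#'   a `"pawtrigger_qc"` message attribute.
#' @export
qc_trials <- function(records, max_mean_latency_ms = 500,
                      drop_zero_event = TRUE, required_days = NULL) {
  keep <- vapply(records, function(r) {
    if (drop_zero_event && nrow(r$events) == 0L) return(FALSE)
    if (nrow(r$events) > 0L) {
      lat <- mean(r$events$dispatch_time_ms - r$events$frame_time_ms)
      if (is.finite(lat) && lat > max_mean_latency_ms) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- records[keep]
  if (!is.null(required_days)) {
    mice <- unique(vapply(out, `[[`, "", "mouse"))
    ok_mice <- mice[vapply(mice, function(m) {
      days <- unique(vapply(out[vapply(out, `[[`, "", "mouse") == m],
                            function(r) r$day, integer(1)))
      all(required_days %in% days)
    }, logical(1))]
    out <- out[vapply(out, `[[`, "", "mouse") %in% ok_mice]
  }
  structure(out, class = "trial_collection")
}
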