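#' Mock GPIO feedback device
#'
#' Stands in for the USB-GPIO breakout board that drives the red feedback
#' LED, the water valve, and the green trial cue. It records a millisecond-
#' stamped timeline of channel on/off events and simulates a fixed
#' command-to-device latency. Any real board can be adapted behind the same
#' `set_channel(name, level, time)` surface.
#'
#' @param latency_ms Injected command-to-device latency, ms (the hardware
#'   leg; real boards show well under a millisecond).
#' @param fail_channels Character vector of channels that silently fail
#'   (device-failure simulation; failures are counted, not fatal).
#' @return A `feedback_device` environment.
#' @export
mock_device <- function(latency_ms = 0.31, fail_channels = character()) {
  dev <- new.env(parent = emptyenv())
  dev$latency_ms <- latency_ms
  dev$fail_channels <- fail_channels
  dev$timeline <- list()
  dev$misses <- 0L
  dev$set_channel <- function(name, level, time) {
    if (name %in% dev$fail_channels) {
      dev$misses <- dev$misses + 1L
      return(invisible(NULL))
    }
    dev$timeline[[length(dev$timeline) + 1L]] <-
      list(channel = name, level = level, t_ms = time + dev$latency_ms)
    invisible(NULL)
  }
  class(dev) <- "feedback_device"
  dev
}

#' @export
print.feedback_device <- function(x, ...) {
  cat(sprintf("<feedback_device> latency %g ms, %d timeline entries, %d misses\n",
              x$latency_ms, length(x$timeline), x$misses))
  invisible(x)
}

#' Dispatch feedback for a trigger
#'
#' Schedules the feedback pulses a trigger earns: the red LED for
#' `led_pulse` ms in both modes, plus the water valve for `water_pulse` ms
#' on training trials only (baseline trials keep the LED flash but never
#' water). LED and water onsets are simultaneous. Dispatch is modeled as
#' asynchronous: it adds only the device latency to the decision time and is
#' independent of any persistence work.
#'
#' @param device A [mock_device()].
#' @param trigger_time Decision time stamp of the trigger, ms.
#' @param mode `"training"` or `"baseline"`.
#' @param config A [criterion_config()] supplying pulse lengths.
#' @return A one-row tibble feedback event: `trigger_time`, `dispatch_time`,
#'   `channels`, `led_pulse`, `water_pulse`.
#' @export
dispatch_feedback <- function(device, trigger_time,
                              mode = c("training", "baseline"),
                              config = criterion_config()) {
  mode <- match.arg(mode)
  dispatch_time <- trigger_time + device$latency_ms
  device$set_channel("red_led", 1, trigger_time)
  device$set_channel("red_led", 0, trigger_time + config$led_pulse)
  water <- mode == "training"
  if (water) {
    device$set_channel("water", 1, trigger_time)
    device$set_channel("water", 0, trigger_time + config$water_pulse)
  }
  tibble(trigger_time = trigger_time, dispatch_time = dispatch_time,
         channels = if (water) "red_led+water" else "red_led",
         led_pulse = config$led_pulse,
         water_pulse = if (water) config$water_pulse else NA_real_)
}

#' Set the trial-type cue
#'
#' The green cue LED is held on for the entire duration of a training trial
#' and stays off throughout baseline trials.
#'
#' @param device A [mock_device()].
#' @param mode `"training"` or `"baseline"`.
#' @param t_start,t_end Trial start and end times, ms.
#' @return Logical: whether the cue is on for this trial.
#' @export
set_cue <- function(device, mode = c("training", "baseline"),
                    t_start = 0, t_end = NULL) {
  mode <- match.arg(mode)
  on <- mode == "training"
  if (on) {
    device$set_channel("green_cue", 1, t_start)
    if (!is.null(t_end)) device$set_channel("green_cue", 0, t_end)
  }
  on
}

#' Device timeline as a tidy on/off table
#'
#' Collapses the raw channel event list of a [mock_device()] into pulses:
#' one row per (channel, on, off) with millisecond stamps.
#'
#' @param device A [mock_device()].
#' @return A tibble `channel`, `t_on_ms`, `t_off_ms`.
#' @export
device_timeline <- function(device) {
  if (length(device$timeline) == 0L)
    return(tibble(channel = character(), t_on_ms = numeric(),
                  t_off_ms = numeric()))
  raw <- bind_rows(lapply(device$timeline, as_tibble))
  raw <- arrange(raw, .data$channel, .data$t_ms)
  out <- raw |>
    group_by(.data$channel) |>
    summarise(t_on_ms = list(.data$t_ms[.data$level == 1]),
              t_off_ms = list(.data$t_ms[.data$level == 0]),
              .groups = "drop")
  rows <- purrr::pmap(out, function(channel, t_on_ms, t_off_ms) {
    n <- length(t_on_ms)
    tibble(channel = channel, t_on_ms = t_on_ms,
           t_off_ms = c(t_off_ms, rep(NA_real_, max(0, n - length(t_off_ms))))[seq_len(n)])
  })
  arrange(bind_rows(rows), .data$t_on_ms)
}
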