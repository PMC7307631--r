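#' Trigger criterion configuration
#'
#' Bundles every threshold and timing constant used by the trigger engine.
#' The defaults are the operating constants of the head-fixed forepaw
#' reinforcement rig this package models: a left-paw vertical displacement
#' between 5 and 100 pixels (inclusive) across a frame pair earns feedback,
#' provided the right paw moved no more than 10 pixels vertically, the pose
#' confidence exceeds 0.20, and no trigger fired in the preceding 300 ms.
#'
#' @param min_left Minimum left-paw vertical displacement, pixels (inclusive).
#' @param max_left Maximum left-paw vertical displacement, pixels (inclusive);
#'   guards against tracking jumps across the screen.
#' @param max_right Contralateral (right-paw) displacement limit, pixels
#'   (inclusive: a displacement of exactly `max_right` does not veto).
#' @param confidence_min Pose-confidence gate; the aggregated keypoint
#'   confidence must be strictly greater than this value.
#' @param refractory Dead time after each trigger, ms. Re-arms only once
#'   strictly more than `refractory` ms have elapsed.
#' @param led_pulse Red feedback LED pulse length, ms.
#' @param water_pulse Water-reward valve pulse length, ms (training trials).
#' @param confidence_aggregate How the 8 keypoint confidences of the pair's
#'   second frame are aggregated before the gate: `"mean"` or `"min"`.
#' @param confidence_frames Whether the gate applies to the pair's second
#'   frame only (`"second"`) or to both frames (`"both"`, using the worse
#'   aggregate of the two).
#'
#' @return A `criterion_config` list.
#' @export
#' @examples
#' criterion_config()
#' criterion_config(min_left = 8, refractory = 500)
criterion_config <- function(min_left = 5,
                             max_left = 100,
                             max_right = 10,
                             confidence_min = 0.20,
                             refractory = 300,
                             led_pulse = 200,
                             water_pulse = 150,
                             confidence_aggregate = c("mean", "min"),
                             confidence_frames = c("second", "both")) {
  confidence_aggregate <- match.arg(confidence_aggregate)
  confidence_frames <- match.arg(confidence_frames)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      abort_config("criterion field `%s` must be a single finite number", nm)
    as.numeric(x)
  }
  cfg <- list(
    min_left = num1(min_left, "min_left"),
    max_left = num1(max_left, "max_left"),
    max_right = num1(max_right, "max_right"),
    confidence_min = num1(confidence_min, "confidence_min"),
    refractory = num1(refractory, "refractory"),
    led_pulse = num1(led_pulse, "led_pulse"),
    water_pulse = num1(water_pulse, "water_pulse"),
    confidence_aggregate = confidence_aggregate,
    confidence_frames = confidence_frames
  )
  if (cfg$min_left <= 0 || cfg$min_left > cfg$max_left)
    abort_config("need 0 < min_left <= max_left (got %g, %g)",
                 cfg$min_left, cfg$max_left)
  if (cfg$max_right <= 0)
    abort_config("max_right must be > 0 (got %g)", cfg$max_right)
  if (cfg$confidence_min < 0 || cfg$confidence_min >= 1)
    abort_config("confidence_min must lie in [0, 1) (got %g)",
                 cfg$confidence_min)
  for (nm in c("refractory", "led_pulse", "water_pulse"))
    if (cfg[[nm]] <= 0)
      abort_config("`%s` must be > 0 (got %g)", nm, cfg[[nm]])
  structure(cfg, class = "criterion_config")
}

#' @export
print.criterion_config <- function(x, ...) {
  cat("<criterion_config>\n")
  cat(sprintf("  left paw:  %g..%g px (inclusive)\n", x$min_left, x$max_left))
  cat(sprintf("  right paw: <= %g px\n", x$max_right))
  cat(sprintf("  confidence: > %g (%s over %s frame)\n", x$confidence_min,
              x$confidence_aggregate, x$confidence_frames))
  cat(sprintf("  refractory %g ms | LED %g ms | water %g ms\n",
              x$refractory, x$led_pulse, x$water_pulse))
  invisible(x)
}

#' Session timing configuration
#'
#' Timing layout of one trial: an initial buffer during which frames are
#' analyzed but nothing is persisted or rewarded (it lets throughput
#' stabilize), a short wait after the buffer before persistence begins, and
#' the recording window proper. Defaults give the nominal 130 s trial:
#' 10 s buffer + 120 s of recorded movement and feedback data.
#'
#' @param buffer_duration Buffer period, seconds.
#' @param post_buffer_wait Pause between buffer end and persistence start, ms.
#' @param recording_duration Recorded window, seconds.
#' @param input_frame_rate Nominal camera input rate, Hz.
#' @param resolution Frame size, pixels (length-2 `c(width, height)` or one
#'   number for square frames).
#' @param processing_delay_ms Simulated per-pair pose-estimation plus decision
#'   latency, ms; the decision time stamp of a pair is its second frame's
#'   acquisition time plus this delay.
#'
#' @return A `session_config` list.
#' @export
#' @examples
#' session_config()
session_config <- function(buffer_duration = 10,
                           post_buffer_wait = 100,
                           recording_duration = 120,
                           input_frame_rate = 200,
                           resolution = c(256, 256),
                           processing_delay_ms = 30) {
  if (length(resolution) == 1L) resolution <- rep(resolution, 2L)
  vals <- list(buffer_duration = buffer_duration,
               post_buffer_wait = post_buffer_wait,
               recording_duration = recording_duration,
               input_frame_rate = input_frame_rate,
               processing_delay_ms = processing_delay_ms)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      abort_config("session field `%s` must be a single finite number", nm)
  }
  if (buffer_duration < 0) abort_config("buffer_duration must be >= 0")
  if (post_buffer_wait < 0) abort_config("post_buffer_wait must be >= 0")
  if (recording_duration <= 0) abort_config("recording_duration must be > 0")
  if (input_frame_rate <= 0) abort_config("input_frame_rate must be > 0")
  if (processing_delay_ms < 0) abort_config("processing_delay_ms must be >= 0")
  if (any(resolution < 64))
    abort_config("resolution must be at least 64x64 pixels")
  structure(list(
    buffer_duration = as.numeric(buffer_duration),
    post_buffer_wait = as.numeric(post_buffer_wait),
    recording_duration = as.numeric(recording_duration),
    input_frame_rate = as.numeric(input_frame_rate),
    resolution = as.integer(resolution),
    processing_delay_ms = as.numeric(processing_delay_ms)
  ), class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf("  trial: %g s buffer + %g ms wait + %g s recording (%g s total)\n",
              x$buffer_duration, x$post_buffer_wait, x$recording_duration,
              x$buffer_duration + x$recording_duration))
  cat(sprintf("  input %g Hz, %dx%d px, processing delay %g ms\n",
              x$input_frame_rate, x$resolution[1], x$resolution[2],
              x$processing_delay_ms))
  invisible(x)
}

# time (ms) at which persistence (and feedback) begins
persist_start_ms <- function(config) {
  config$buffer_duration * 1000 + config$post_buffer_wait
}
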