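#' Motion script for a synthetic session
#'
#' Declarative description of one synthetic head-fixed forepaw session: which
#' paw reaches when and how far, whether grooming-like co-movements occur,
#' and the imperfections of acquisition (frame drops, timestamp jitter).
#' A script plus its seed fully determines the generated session —
#' regeneration is bit-identical.
#'
#' Default acquisition values mirror the rig being emulated: 130 s trials
#' streamed at a nominal 200 Hz input rate of which roughly a third of frames
#' survive processing (drop probability 0.67, giving a realized throughput
#' near 66 Hz), and inter-frame timestamp jitter of 4.16 ms SD.
#'
#' @param duration Session length, seconds.
#' @param frame_rate Nominal camera frame rate, Hz.
#' @param reach_events Data frame with columns `onset` (s), `paw`
#'   (`"left"`/`"right"`), `amplitude` (px) and `rise` (s, the half-duration
#'   of the half-cosine excursion). `NULL` for no scripted reaches.
#' @param baseline_jitter_sd Per-frame, per-digit positional noise SD, px.
#' @param grooming_intervals Data frame with columns `start`, `end` (s):
#'   windows in which both paws co-move with correlated vertical excursions.
#' @param grooming_amplitude Peak grooming excursion, px.
#' @param grooming_freq Grooming oscillation frequency, Hz.
#' @param drop_probability Per-frame probability that the frame arrives as a
#'   data-less placeholder (a dropped frame).
#' @param timestamp_jitter_sd Timestamp noise SD, ms.
#' @param width,height Frame size, pixels.
#' @param seed Integer seed; all randomness of the session flows from it.
#'
#' @return A `motion_script` object.
#' @export
#' @examples
#' sc <- motion_script(duration = 10, frame_rate = 100,
#'                     reach_events = reach_schedule(c(2, 5, 8), amplitude = 20))
#' sc
motion_script <- function(duration = 130,
                          frame_rate = 200,
                          reach_events = NULL,
                          baseline_jitter_sd = 0.5,
                          grooming_intervals = NULL,
                          grooming_amplitude = 15,
                          grooming_freq = 4,
                          drop_probability = 0.67,
                          timestamp_jitter_sd = 4.16,
                          width = 256,
                          height = 256,
                          seed = 1L) {
  for (nm in c("duration", "frame_rate", "baseline_jitter_sd",
               "grooming_amplitude", "grooming_freq", "drop_probability",
               "timestamp_jitter_sd", "width", "height")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      abort_config("motion_script field `%s` must be a finite number >= 0", nm)
  }
  if (duration <= 0 || frame_rate <= 0)
    abort_config("duration and frame_rate must be > 0")
  if (drop_probability > 1)
    abort_config("drop_probability must lie in [0, 1]")
  if (width < 64 || height < 64)
    abort_config("frame size must be at least 64x64 px")

  reach_events <- normalize_reaches(reach_events, duration)
  grooming_intervals <- normalize_grooming(grooming_intervals, duration)

  structure(list(
    duration = as.numeric(duration),
    frame_rate = as.numeric(frame_rate),
    reach_events = reach_events,
    baseline_jitter_sd = as.numeric(baseline_jitter_sd),
    grooming_intervals = grooming_intervals,
    grooming_amplitude = as.numeric(grooming_amplitude),
    grooming_freq = as.numeric(grooming_freq),
    drop_probability = as.numeric(drop_probability),
    timestamp_jitter_sd = as.numeric(timestamp_jitter_sd),
    width = as.integer(width),
    height = as.integer(height),
    seed = as.integer(seed)
  ), class = "motion_script")
}

normalize_reaches <- function(reach_events, duration) {
  if (is.null(reach_events) || (is.data.frame(reach_events) && nrow(reach_events) == 0L))
    return(tibble(onset = numeric(), paw = character(),
                  amplitude = numeric(), rise = numeric()))
  reach_events <- as_tibble(reach_events)
  if (!all(c("onset", "paw", "amplitude") %in% names(reach_events)))
    abort_config("reach_events needs columns onset, paw, amplitude")
  if (!"rise" %in% names(reach_events)) reach_events$rise <- 0.1
  if (!all(reach_events$paw %in% c("left", "right")))
    abort_config("reach paw must be 'left' or 'right'")
  if (any(!is.finite(reach_events$onset)) ||
      any(reach_events$onset < 0) || any(reach_events$onset >= duration))
    abort_config("reach onsets must lie in [0, duration)")
  if (any(!is.finite(reach_events$amplitude)) || any(reach_events$amplitude < 0))
    abort_config("reach amplitudes must be finite and >= 0")
  if (any(reach_events$rise <= 0))
    abort_config("reach rise durations must be > 0")
  arrange(reach_events[c("onset", "paw", "amplitude", "rise")], .data$onset)
}

normalize_grooming <- function(grooming, duration) {
  if (is.null(grooming) || (is.data.frame(grooming) && nrow(grooming) == 0L))
    return(tibble(start = numeric(), end = numeric()))
  grooming <- as_tibble(grooming)
  if (!all(c("start", "end") %in% names(grooming)))
    abort_config("grooming_intervals needs columns start, end")
  if (any(grooming$start < 0) || any(grooming$end > duration) ||
      any(grooming$end <= grooming$start))
    abort_config("grooming intervals must satisfy 0 <= start < end <= duration")
  arrange(grooming[c("start", "end")], .data$start)
}

#' Build a reach schedule
#'
#' Convenience constructor for the `reach_events` table of [motion_script()].
#'
#' @param onsets Reach onset times, seconds.
#' @param paw `"left"` or `"right"`, recycled across onsets.
#' @param amplitude Reach amplitude, pixels, recycled.
#' @param rise Half-duration of the half-cosine excursion, seconds, recycled.
#' @return A tibble suitable for `motion_script(reach_events = ...)`.
#' @export
reach_schedule <- function(onsets, paw = "left", amplitude = 20, rise = 0.1) {
  tibble(onset = onsets,
         paw = rep_len(paw, length(onsets)),
         amplitude = rep_len(amplitude, length(onsets)),
         rise = rep_len(rise, length(onsets)))
}

#' @export
print.motion_script <- function(x, ...) {
  cat("<motion_script>\n")
  cat(sprintf("  %g s @ %g Hz (%dx%d px), seed %d\n", x$duration,
              x$frame_rate, x$width, x$height, x$seed))
  cat(sprintf("  %d reach(es), %d grooming interval(s)\n",
              nrow(x$reach_events), nrow(x$grooming_intervals)))
  cat(sprintf("  drop p=%g, jitter sd %g px / %g ms\n", x$drop_probability,
              x$baseline_jitter_sd, x$timestamp_jitter_sd))
  invisible(x)
}

# Resting digit geometry: paw centers at fixed fractions of the frame, with
# the four digit tips fanned horizontally. Returns an 8 x 2 matrix (x, y)
# in DIGITS order.
rest_positions <- function(width, height) {
  # digit spacing floored at 8 px so rendered markers stay separable at the
  # smallest supported resolutions
  spread <- max(8, width / 32)
  left_x <- width * 0.25 + spread * (-1.5:1.5)
  right_x <- width * 0.75 + spread * (-1.5:1.5)
  y <- rep(height * 0.60, 4)
  cbind(x = c(left_x, right_x), y = c(y, y))
}

# Half-cosine reach pulse: 0 -> amplitude over `rise` seconds and back over
# another `rise` seconds. Vectorized over t (seconds since reach onset).
reach_pulse <- function(t, amplitude, rise) {
  out <- numeric(length(t))
  up <- t >= 0 & t < rise
  down <- t >= rise & t < 2 * rise
  out[up] <- amplitude * 0.5 * (1 - cos(pi * t[up] / rise))
  out[down] <- amplitude * 0.5 * (1 + cos(pi * (t[down] - rise) / rise))
  out
}

#' Generate a ground-truthed pose trace from a motion script
#'
#' Turns a [motion_script()] into a per-frame trace of the 8 digit-tip
#' keypoints (4 per forepaw) with timestamps, dropped-frame placeholders and
#' per-keypoint confidences, plus the noise-free ground truth needed to
#' verify every downstream stage. Reaches appear as vertical (decreasing-y,
#' i.e. upward on screen) half-cosine excursions of all four digits of the
#' scripted paw moving coherently; grooming intervals add correlated
#' oscillations to both paws.
#'
#' Coordinates are in pixels with the image convention: origin at the
#' top-left corner, y increasing downward; frame indices are 1-based.
#'
#' @param script A [motion_script()].
#' @return A list with elements:
#'   * `trace`: tibble with one row per emitted frame — `frame`, `t_ms`,
#'     `dropped`, and `<digit>_x`, `<digit>_y`, `<digit>_lik` columns for the
#'     8 digits (NA on dropped frames).
#'   * `truth`: list with the noise-free `positions` tibble, `dropped_frames`,
#'     `reach_frames` (frame index nearest each scripted reach onset),
#'     `led_flash_onsets` (filled by [render_frames()]), and the `script`.
#' @export
#' @examples
#' sc <- motion_script(duration = 5, frame_rate = 50, drop_probability = 0,
#'                     reach_events = reach_schedule(2), seed = 7)
#' sess <- generate_pose_trace(sc)
#' dim(sess$trace)
generate_pose_trace <- function(script) {
  if (!inherits(script, "motion_script"))
    abort_config("`script` must be a motion_script object")
  n <- round(script$duration * script$frame_rate)
  if (n < 1L) abort_config("script describes an empty session")

  withr::with_seed(script$seed, {
    t_nominal <- (seq_len(n) - 1) / script$frame_rate * 1000
    t_ms <- t_nominal + rnorm(n, 0, script$timestamp_jitter_sd)
    t_ms <- cummax(t_ms)  # enforce a monotone acquisition clock
    dropped <- runif(n) < script$drop_probability

    rest <- rest_positions(script$width, script$height)
    t_s <- t_nominal / 1000

    # vertical excursion per paw (pixels, subtracted from resting y)
    dy <- matrix(0, n, 2, dimnames = list(NULL, c("left", "right")))
    if (nrow(script$reach_events) > 0) {
      for (i in seq_len(nrow(script$reach_events))) {
        ev <- script$reach_events[i, ]
        dy[, ev$paw] <- dy[, ev$paw] +
          reach_pulse(t_s - ev$onset, ev$amplitude, ev$rise)
      }
    }
    if (nrow(script$grooming_intervals) > 0) {
      for (i in seq_len(nrow(script$grooming_intervals))) {
        gi <- script$grooming_intervals[i, ]
        inside <- t_s >= gi$start & t_s < gi$end
        osc <- script$grooming_amplitude *
          0.5 * (1 - cos(2 * pi * script$grooming_freq * (t_s[inside] - gi$start)))
        dy[inside, "left"] <- dy[inside, "left"] + osc
        dy[inside, "right"] <- dy[inside, "right"] + 0.9 * osc
      }
    }

    true_x <- matrix(rest[, "x"], n, 8, byrow = TRUE)
    true_y <- matrix(rest[, "y"], n, 8, byrow = TRUE)
    true_y[, 1:4] <- true_y[, 1:4] - dy[, "left"]
    true_y[, 5:8] <- true_y[, 5:8] - dy[, "right"]

    obs_x <- true_x + matrix(rnorm(n * 8, 0, script$baseline_jitter_sd), n, 8)
    obs_y <- true_y + matrix(rnorm(n * 8, 0, script$baseline_jitter_sd), n, 8)
    obs_x <- pmin(pmax(obs_x, 1), script$width)
    obs_y <- pmin(pmax(obs_y, 1), script$height)
    lik <- matrix(1, n, 8)

    obs_x[dropped, ] <- NA_real_
    obs_y[dropped, ] <- NA_real_
    lik[dropped, ] <- NA_real_
  })

  colnames(obs_x) <- digit_cols("x")
  colnames(obs_y) <- digit_cols("y")
  colnames(lik) <- digit_cols("lik")
  trace <- tibble(frame = seq_len(n), t_ms = t_ms, dropped = dropped)
  trace <- dplyr::bind_cols(trace, as_tibble(obs_x), as_tibble(obs_y),
                            as_tibble(lik))
  # interleave columns per digit for readability
  trace <- trace[, c("frame", "t_ms", "dropped",
                     as.vector(t(cbind(digit_cols("x"), digit_cols("y"),
                                       digit_cols("lik")))))]

  colnames(true_x) <- digit_cols("x")
  colnames(true_y) <- digit_cols("y")
  positions <- dplyr::bind_cols(tibble(frame = seq_len(n), t_ms = t_ms),
                                as_tibble(true_x), as_tibble(true_y))

  reach_frames <- if (nrow(script$reach_events) > 0) {
    vapply(script$reach_events$onset,
           function(o) which.min(abs(t_s - o)), integer(1))
  } else integer()

  list(
    trace = trace,
    truth = list(
      positions = positions,
      dropped_frames = which(dropped),
      reach_frames = reach_frames,
      led_flash_onsets = integer(),
      script = script
    )
  )
}
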