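#' Build an LED intensity trace with baseline statistics
#'
#' Wraps a per-frame ROI mean-intensity vector with the baseline mean and SD
#' needed for contrast-threshold flash detection. Because throughput is
#' unstable early in a trial (frames drop in bursts before roughly the 800th
#' frame), detection skips an initial window. The baseline is computed from
#' post-skip frames; when trigger times are supplied, frames inside a guard
#' window around each trigger are excluded so the flashes themselves do not
#' inflate the background statistics. A zero-variance baseline is floored at
#' an epsilon SD to avoid a degenerate threshold.
#'
#' @param intensity Per-frame ROI mean intensity (NA allowed on dropped
#'   frames).
#' @param t_ms Optional per-frame timestamps (required for time-based guard
#'   windows and [ground_truth_latency()]).
#' @param skip_frames Frames 1..`skip_frames` are never searched (default
#'   800).
#' @param guard_events Trigger/dispatch times (ms) around which baseline
#'   frames are excluded.
#' @param guard_ms Half-width of the exclusion window before, and full width
#'   after, each guard event: frames in `[t - guard_ms/4, t + guard_ms]` are
#'   excluded.
#' @param roi Optional ROI annotation (kept for reporting).
#' @param eps_sd Epsilon SD floor.
#' @return An `led_trace` object.
#' @export
led_trace <- function(intensity, t_ms = NULL, skip_frames = 800,
                      guard_events = NULL, guard_ms = 500, roi = NULL,
                      eps_sd = 1e-6) {
  n <- length(intensity)
  if (skip_frames < 0) abort_config("skip_frames must be >= 0")
  if (n <= skip_frames)
    abort_input("trace (%d frames) is not longer than skip_frames (%d)",
                n, skip_frames)
  base_idx <- seq.int(skip_frames + 1L, n)
  if (!is.null(guard_events) && length(guard_events) > 0) {
    if (is.null(t_ms)) abort_input("guard_events require per-frame t_ms")
    guarded <- rep(FALSE, n)
    for (g in guard_events)
      guarded <- guarded | (t_ms >= g - guard_ms / 4 & t_ms <= g + guard_ms)
    base_idx <- base_idx[!guarded[base_idx]]
  }
  base <- intensity[base_idx]
  base <- base[is.finite(base)]
  if (length(base) < 2L)
    abort_input("no usable baseline frames after skip and guard windows")
  bsd <- sd(base)
  if (!is.finite(bsd) || bsd < eps_sd) {
    warning("zero-variance LED baseline; flooring SD at epsilon")
    bsd <- eps_sd
  }
  structure(list(intensity = as.numeric(intensity), t_ms = t_ms,
                 skip_frames = as.integer(skip_frames),
                 baseline_mean = mean(base), baseline_sd = bsd,
                 roi = roi),
            class = "led_trace")
}

#' @export
print.led_trace <- function(x, ...) {
  cat(sprintf("<led_trace> %d frames, skip %d, baseline %.2f +/- %.3f\n",
              length(x$intensity), x$skip_frames, x$baseline_mean,
              x$baseline_sd))
  invisible(x)
}

#' Detect LED flash onsets by contrast threshold
#'
#' A flash onset is the first frame (after the skip window) on which the ROI
#' intensity exceeds `baseline_mean + k_sd * baseline_sd`; the detector then
#' disarms and re-arms only after the intensity returns below the threshold,
#' so each flash is reported exactly once. Onset time is the timestamp of
#' the crossing frame — frame-level resolution, no interpolation. Frames at
#' or before `skip_frames` are never reported. Adding a constant to the
#' whole trace leaves the detections unchanged (the threshold is relative to
#' the baseline mean).
#'
#' @param trace An [led_trace()].
#' @param k_sd Threshold criterion in baseline SDs (default 3).
#' @return Integer vector of onset frame indices (1-based).
#' @export
#' @examples
#' y <- rep(c(49, 51), 500)
#' y[900:913] <- 80
#' detect_flashes(led_trace(y, skip_frames = 800))
detect_flashes <- function(trace, k_sd = 3) {
  thr <- trace$baseline_mean + k_sd * trace$baseline_sd
  y <- trace$intensity
  n <- length(y)
  onsets <- integer()
  armed <- TRUE
  for (i in seq.int(trace$skip_frames + 1L, n)) {
    v <- y[i]
    if (!is.finite(v)) next  # dropped frame: state unchanged
    if (armed && v > thr) {
      onsets <- c(onsets, i)
      armed <- FALSE
    } else if (!armed && v < thr) {
      armed <- TRUE
    }
  }
  onsets
}

#' Time-stamp feedback latency of a trial
#'
#' Latency measured from the software's own clocks: for each trigger event,
#' the time between the acquisition of the frame on which the criterion
#' movement arrived and the dispatch of the feedback command.
#'
#' @param record A `trial_record` (or any tibble with `frame_time_ms` and
#'   `dispatch_time_ms` columns).
#' @return A `latency_result` (method `"timestamp"`): per-event latencies
#'   with mean and SD; zero-event trials yield an empty result flagged
#'   `empty = TRUE`.
#' @export
timestamp_latency <- function(record) {
  ev <- if (inherits(record, "trial_record")) record$events else record
  if (nrow(ev) == 0L) {
    return(structure(list(latencies = numeric(), mean = NA_real_,
                          sd = NA_real_, method = "timestamp", empty = TRUE,
                          flagged = integer()),
                     class = "latency_result"))
  }
  lat <- ev$dispatch_time_ms - ev$frame_time_ms
  flagged <- which(lat < 0)
  new_latency_result(lat, "timestamp", flagged)
}

new_latency_result <- function(lat, method, flagged = integer(),
                               unmatched = integer()) {
  structure(list(latencies = lat,
                 mean = mean(lat[lat >= 0]),
                 sd = sd(lat[lat >= 0]),
                 method = method, empty = length(lat) == 0L,
                 flagged = flagged, unmatched = unmatched),
            class = "latency_result")
}

#' @export
print.latency_result <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<latency_result> %s: empty (no events)\n", x$method))
  } else {
    cat(sprintf("<latency_result> %s: n=%d, mean %.2f ms (SD %.2f)\n",
                x$method, length(x$latencies), x$mean, x$sd))
    if (length(x$flagged)) cat(sprintf("  %d negative latencies flagged as alignment errors\n", length(x$flagged)))
    if (length(x$unmatched)) cat(sprintf("  %d unmatched events\n", length(x$unmatched)))
  }
  invisible(x)
}

#' Ground-truth feedback latency from detected LED onsets
#'
#' The video-based counterpart of [timestamp_latency()]: for each trigger
#' event, the time between the start of the frame on which the criterion
#' movement was detected and the detected LED-contrast crossing. Each event
#' is matched to the nearest onset that follows it within `window_ms`;
#' unmatched events are flagged rather than dropped silently, and negative
#' latencies are flagged as alignment errors.
#'
#' @param onsets Onset frame indices from [detect_flashes()].
#' @param events Trigger events (tibble with `frame_time_ms`).
#' @param t_ms Per-frame timestamps of the video, ms.
#' @param window_ms Maximum onset-minus-event gap considered a match.
#' @return A `latency_result` (method `"ground_truth"`).
#' @export
ground_truth_latency <- function(onsets, events, t_ms, window_ms = 1000) {
  if (length(onsets) > nrow(events))
    abort_input("alignment error: %d LED onsets but only %d trigger events",
                length(onsets), nrow(events))
  onset_times <- t_ms[onsets]
  lat <- numeric(0)
  unmatched <- integer(0)
  used <- rep(FALSE, length(onset_times))
  for (i in seq_len(nrow(events))) {
    ft <- events$frame_time_ms[i]
    cand <- which(!used & onset_times >= ft &
                  onset_times - ft <= window_ms)
    if (length(cand) == 0L) {
      unmatched <- c(unmatched, i)
      next
    }
    j <- cand[which.min(onset_times[cand] - ft)]
    used[j] <- TRUE
    lat <- c(lat, onset_times[j] - ft)
  }
  new_latency_result(lat, "ground_truth", which(lat < 0), unmatched)
}

#' Compare time-stamp and ground-truth latency by paired t test
#'
#' Takes per-trial mean latencies measured both ways and tests whether the
#' two methods disagree, using a standard paired t test. All-zero
#' differences are reported as a zero-variance case rather than an error.
#'
#' @param paired Tibble with columns `timestamp` and `ground_truth`, one row
#'   per trial.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_difference`,
#'   `zero_variance`.
#' @export
compare_latency_methods <- function(paired) {
  if (!all(c("timestamp", "ground_truth") %in% names(paired)))
    abort_input("`paired` needs columns timestamp and ground_truth")
  if (nrow(paired) < 2L)
    abort_input("insufficient data: need >= 2 paired trials, got %d",
                nrow(paired))
  d <- paired$ground_truth - paired$timestamp
  if (sd(d) == 0) {
    return(tibble(t = if (mean(d) == 0) 0 else Inf, df = length(d) - 1L,
                  p = NA_real_, mean_difference = mean(d),
                  zero_variance = TRUE))
  }
  tt <- t.test(paired$ground_truth, paired$timestamp, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_difference = unname(tt$estimate),
         zero_variance = FALSE)
}

#' Nyquist sampling limit of a frame stream
#'
#' By the Nyquist–Shannon sampling theorem the frame rate must be at least
#' twice the frequency of the fastest movement sampled; a stream processed
#' at `rate` Hz can therefore represent movement frequencies up to
#' `rate / 2`, reported to two decimals.
#'
#' @param rate Output (processed) frame rate, Hz.
#' @return Maximum detectable movement frequency, Hz.
#' @export
#' @examples
#' nyquist_limit(65.59)
nyquist_limit <- function(rate) {
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate < 0))
    abort_input("frame rate must be finite and >= 0")
  round(rate / 2, 2)
}

#' Convert a pixel displacement to millimetres
#'
#' Spatial calibration from a measured scene scale (e.g. the physical width
#' of the animal's tube floor cross-referenced with its width in pixels).
#'
#' @param displacement Displacement, pixels.
#' @param scale Scene scale, mm per pixel (> 0).
#' @return Displacement in mm.
#' @export
#' @examples
#' px_to_mm(5, 44 / 256)
px_to_mm <- function(displacement, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    abort_input("calibration scale must be a single positive number (mm/px)")
  displacement * scale
}
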