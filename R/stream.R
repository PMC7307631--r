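#' Open a replay frame source
#'
#' Wraps a generated (or reloaded) session so it can be consumed one frame
#' record at a time, exactly as a live camera source would deliver it:
#' records arrive in index order with their acquisition timestamps, dropped
#' frames arrive as placeholders, and exhaustion is signaled rather than
#' raised.
#'
#' @param trace Pose trace tibble (see [generate_pose_trace()]); its rows are
#'   the emitted frames.
#' @param frames Optional `frame_stack` whose images are attached to the
#'   records (for image-based pose backends).
#' @param timestamps Optional override of `trace$t_ms` (must be monotone and
#'   match the frame count).
#' @return A `frame_source` environment with `$next_record()`.
#' @export
#' @examples
#' sess <- generate_pose_trace(motion_script(duration = 1, frame_rate = 20,
#'                                           drop_probability = 0, seed = 1))
#' src <- open_replay_source(sess$trace)
#' rec <- src$next_record()
#' rec$index
open_replay_source <- function(trace, frames = NULL, timestamps = NULL) {
  if (!is.data.frame(trace))
    abort_input("replay source needs a pose trace data frame")
  # an empty trace is a legal source that is exhausted immediately
  if (!is.null(timestamps)) {
    if (length(timestamps) != nrow(trace))
      abort_input("length mismatch: %d frames but %d timestamps",
                  nrow(trace), length(timestamps))
    if (is.unsorted(timestamps))
      abort_input("timestamps must be non-decreasing")
    trace$t_ms <- timestamps
  }
  if (!is.null(frames) && dim(frames$frames)[1] != nrow(trace))
    abort_input("length mismatch: %d frames in stack, %d trace rows",
                dim(frames$frames)[1], nrow(trace))

  xs <- as.matrix(trace[, digit_cols("x")])
  ys <- as.matrix(trace[, digit_cols("y")])
  lk <- as.matrix(trace[, digit_cols("lik")])
  dropped <- trace$dropped
  t_ms <- trace$t_ms
  n <- nrow(trace)

  src <- new.env(parent = emptyenv())
  src$i <- 0L
  src$n <- n
  src$next_record <- function() {
    if (src$i >= src$n) return(NULL)  # exhaustion signal
    src$i <- src$i + 1L
    i <- src$i
    list(
      index = i,
      acquisition_time = t_ms[i],
      is_placeholder = isTRUE(dropped[i]),
      x = xs[i, ], y = ys[i, ], likelihood = lk[i, ],
      image = if (!is.null(frames) && !dropped[i]) frames$frames[i, , ] else NULL
    )
  }
  class(src) <- "frame_source"
  src
}

#' @export
print.frame_source <- function(x, ...) {
  cat(sprintf("<frame_source> %d/%d frames consumed\n", x$i, x$n))
  invisible(x)
}

#' Take the next non-overlapping frame pair from a source
#'
#' Frames are consumed in batches of two so movement can be compared directly
#' between consecutive received frames: received (non-placeholder) frames
#' form the pairs (1st, 2nd), (3rd, 4th), ... Placeholders encountered along
#' the way are appended to `ledger$drops` and skipped, so a pair formed
#' across a drop is flagged `non_adjacent`. Exhaustion mid-pair discards the
#' unpaired frame and returns `NULL`.
#'
#' @param source A `frame_source`.
#' @param ledger Optional environment collecting `drops` (indices) and
#'   `processed` (count of received frames consumed).
#' @return A list `(first, second, non_adjacent)` or `NULL` on exhaustion.
#' @export
next_pair <- function(source, ledger = NULL) {
  got <- list()
  non_adjacent <- FALSE
  while (length(got) < 2L) {
    rec <- source$next_record()
    if (is.null(rec)) {
      if (!is.null(ledger) && length(got) == 1L)
        ledger$unpaired <- c(ledger$unpaired, got[[1]]$index)
      return(NULL)
    }
    if (rec$is_placeholder) {
      if (!is.null(ledger)) ledger$drops <- c(ledger$drops, rec$index)
      if (length(got) == 1L) non_adjacent <- TRUE
      next
    }
    got[[length(got) + 1L]] <- rec
    if (!is.null(ledger)) ledger$processed <- ledger$processed + 1L
  }
  list(first = got[[1]], second = got[[2]], non_adjacent = non_adjacent)
}

#' Create an empty drop ledger
#' @return An environment with `drops`, `unpaired`, `processed` fields.
#' @export
new_drop_ledger <- function() {
  e <- new.env(parent = emptyenv())
  e$drops <- integer()
  e$unpaired <- integer()
  e$processed <- 0L
  e
}

#' Summarize dropped-frame accounting for a session
#'
#' Placeholder records that lacked data are presumed to be dropped frames.
#' The summary enforces the conservation identity
#' `emitted = processed + dropped` and bins processed-frame throughput at
#' 1 s resolution over the session.
#'
#' @param trace The full emitted trace (including placeholder rows).
#' @return A list with `emitted`, `processed`, `dropped`, and a `throughput`
#'   tibble (`second`, `n_processed`).
#' @export
drop_ledger <- function(trace) {
  emitted <- nrow(trace)
  dropped <- sum(trace$dropped)
  processed <- emitted - dropped
  sec <- floor(trace$t_ms[!trace$dropped] / 1000)
  all_sec <- seq(min(floor(trace$t_ms / 1000), 0), max(floor(trace$t_ms / 1000)))
  counts <- table(factor(sec, levels = all_sec))
  list(
    emitted = emitted,
    processed = processed,
    dropped = dropped,
    throughput = tibble(second = as.numeric(all_sec),
                        n_processed = as.integer(counts))
  )
}

#' Flag buffer-period frames
#'
#' During the initial buffer the movement analysis runs but nothing is saved
#' and no feedback is delivered; after the buffer a short wait is observed
#' before persistence begins. This annotates each frame of a trace with
#' `buffered` (inside the buffer) and `persisted` (at or after
#' buffer end + post-buffer wait).
#'
#' @param trace Pose trace tibble.
#' @param config A [session_config()].
#' @return The trace with logical columns `buffered` and `persisted` added.
#' @export
run_buffer <- function(trace, config = session_config()) {
  buf_end <- config$buffer_duration * 1000
  pers <- persist_start_ms(config)
  mutate(trace,
         buffered = .data$t_ms < buf_end,
         persisted = .data$t_ms >= pers)
}
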