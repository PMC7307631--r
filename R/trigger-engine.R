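#' Paired-frame paw displacement
#'
#' The movement quantity every trigger decision is based on: the absolute
#' change in the mean vertical (y) position of each paw between the two
#' frames of a batch. Vertical means along the image y axis; the absolute
#' value makes upward and downward movement equivalent.
#'
#' @param first,second `pose_estimate` tibbles for the two frames.
#' @param pair_index Index of the pair within the session.
#' @param second_frame_time Acquisition time of the second frame, ms.
#' @param confidence_aggregate `"mean"` or `"min"` over the 8 keypoint
#'   confidences.
#' @param confidence_frames `"second"` (gate on the second frame only) or
#'   `"both"` (the worse of the two frames' aggregates).
#' @return A `paw_displacement` list: `pair_index`, `dy_left`, `dy_right`,
#'   `confidence`, `second_frame_time`.
#' @export
paw_displacement <- function(first, second, pair_index = NA_integer_,
                             second_frame_time = NA_real_,
                             confidence_aggregate = c("mean", "min"),
                             confidence_frames = c("second", "both")) {
  confidence_aggregate <- match.arg(confidence_aggregate)
  confidence_frames <- match.arg(confidence_frames)
  agg <- if (confidence_aggregate == "mean") mean else min
  conf <- agg(second$confidence)
  if (confidence_frames == "both") conf <- min(conf, agg(first$confidence))
  out <- list(
    pair_index = pair_index,
    dy_left = abs(mean_paw_position(second, "left")[["y"]] -
                  mean_paw_position(first, "left")[["y"]]),
    dy_right = abs(mean_paw_position(second, "right")[["y"]] -
                   mean_paw_position(first, "right")[["y"]]),
    confidence = conf,
    second_frame_time = second_frame_time
  )
  structure(out, class = "paw_displacement")
}

#' Fresh trigger-engine state
#' @return A list with `last_trigger_time` (`NA` before any trigger) and
#'   `trigger_count`.
#' @export
engine_state <- function() {
  list(last_trigger_time = NA_real_, trigger_count = 0L)
}

#' Evaluate the selective trigger criterion for one frame pair
#'
#' A pair triggers feedback iff all gates pass:
#' `min_left <= dy_left <= max_left` (inclusive bounds; the upper bound
#' guards against tracking jumping across the screen), `dy_right <=
#' max_right` (contralateral suppression; a displacement of exactly
#' `max_right` does not veto), `confidence > confidence_min`, and the
#' refractory period has elapsed (strictly more than `refractory` ms since
#' the last trigger). The refractory gate is evaluated last but suppresses
#' unconditionally, regardless of movement dynamics; a suppressed passing
#' pair does not reset the refractory clock.
#'
#' @param d A [paw_displacement()] (or any list with `dy_left`, `dy_right`,
#'   `confidence`, `second_frame_time`).
#' @param config A [criterion_config()].
#' @param state An [engine_state()].
#' @return A list `(decision, reason)`; `decision` is `"TRIGGER"` or
#'   `"NO_TRIGGER"` and `reason` is `NA` or one of `below_min`, `above_max`,
#'   `contralateral`, `low_confidence`, `refractory`.
#' @export
#' @examples
#' d <- list(dy_left = 7, dy_right = 2, confidence = 0.9,
#'           second_frame_time = 1000)
#' evaluate_criterion(d, criterion_config(), engine_state())
evaluate_criterion <- function(d, config = criterion_config(),
                               state = engine_state()) {
  reason <- NA_character_
  if (d$dy_left < config$min_left) {
    reason <- "below_min"
  } else if (d$dy_left > config$max_left) {
    reason <- "above_max"
  } else if (d$dy_right > config$max_right) {
    reason <- "contralateral"
  } else if (!(d$confidence > config$confidence_min)) {
    reason <- "low_confidence"
  } else if (!is.na(state$last_trigger_time) &&
             !(d$second_frame_time - state$last_trigger_time >
               config$refractory)) {
    reason <- "refractory"
  }
  list(decision = if (is.na(reason)) "TRIGGER" else "NO_TRIGGER",
       reason = reason)
}

#' Update engine state after a decision
#'
#' A `TRIGGER` decision records the trigger time (arming the refractory
#' period) and increments the trigger count; a `NO_TRIGGER` decision leaves
#' the state untouched.
#'
#' @param state An [engine_state()].
#' @param decision Result of [evaluate_criterion()].
#' @param time Decision reference time (the pair's second-frame time), ms.
#' @return The updated state.
#' @export
update_refractory <- function(state, decision, time) {
  if (decision$decision == "TRIGGER") {
    state$last_trigger_time <- time
    state$trigger_count <- state$trigger_count + 1L
  }
  state
}

# Vectorized pair table over the received frames of a trace: non-overlapping
# pairing (1st,2nd), (3rd,4th), ... of non-placeholder frames. Shared by the
# offline oracle and the per-digit counting so all quantities are computed on
# identical primitives.
pair_table <- function(trace, config = criterion_config()) {
  rec <- trace[!trace$dropped, , drop = FALSE]
  k <- nrow(rec) %/% 2L
  if (k == 0L) {
    return(tibble(pair_index = integer(), first_frame = integer(),
                  second_frame = integer(), frame_time_ms = numeric(),
                  dy_left = numeric(), dy_right = numeric(),
                  confidence = numeric(), non_adjacent = logical()))
  }
  i1 <- seq.int(1L, by = 2L, length.out = k)
  i2 <- i1 + 1L
  Y <- as.matrix(rec[, digit_cols("y")])
  L <- as.matrix(rec[, digit_cols("lik")])
  yl <- rowMeans(Y[, 1:4, drop = FALSE])
  yr <- rowMeans(Y[, 5:8, drop = FALSE])
  agg <- if (config$confidence_aggregate == "mean") {
    rowMeans(L)
  } else {
    apply(L, 1, min)
  }
  conf <- agg[i2]
  if (config$confidence_frames == "both") conf <- pmin(conf, agg[i1])
  tibble(
    pair_index = seq_len(k),
    first_frame = rec$frame[i1],
    second_frame = rec$frame[i2],
    frame_time_ms = rec$t_ms[i2],
    dy_left = abs(yl[i2] - yl[i1]),
    dy_right = abs(yr[i2] - yr[i1]),
    confidence = conf,
    non_adjacent = rec$frame[i2] != rec$frame[i1] + 1L
  )
}

#' Brute-force offline trigger oracle
#'
#' Replays the trigger rules by a straightforward sequential scan over the
#' same non-overlapping pairing the streaming engine uses. Deliberately
#' simple, it is the ground truth the online engine is tested against.
#'
#' @param trace Full pose trace (placeholder rows included).
#' @param config A [criterion_config()].
#' @param persist_start_ms Events before this session time (ms) are part of
#'   the buffer and are neither persisted nor allowed to arm the refractory
#'   clock. 0 evaluates the whole trace.
#' @return A tibble of expected trigger events: `pair_index`,
#'   `second_frame`, `frame_time_ms`, `dy_left`, `dy_right`, `confidence`.
#' @export
offline_oracle <- function(trace, config = criterion_config(),
                           persist_start_ms = 0) {
  pt <- pair_table(trace, config)
  pt <- pt[pt$frame_time_ms >= persist_start_ms, , drop = FALSE]
  hit <- logical(nrow(pt))
  last <- NA_real_
  for (i in seq_len(nrow(pt))) {
    pass <- pt$dy_left[i] >= config$min_left &&
      pt$dy_left[i] <= config$max_left &&
      pt$dy_right[i] <= config$max_right &&
      pt$confidence[i] > config$confidence_min
    if (pass && (is.na(last) ||
                 pt$frame_time_ms[i] - last > config$refractory)) {
      hit[i] <- TRUE
      last <- pt$frame_time_ms[i]
    }
  }
  pt[hit, c("pair_index", "second_frame", "frame_time_ms",
            "dy_left", "dy_right", "confidence")]
}

#' Run the streaming trigger engine over a frame source
#'
#' The online counterpart of [offline_oracle()]: consumes a `frame_source`
#' pair by pair, estimates poses with the supplied backend, evaluates the
#' criterion statefully, and (optionally) dispatches feedback through a
#' device. Frames whose pair completes before `persist_start_ms` are
#' analyzed but neither persisted nor fed back.
#'
#' @param source A `frame_source` from [open_replay_source()].
#' @param config A [criterion_config()].
#' @param backend Function mapping a frame record to a `pose_estimate`;
#'   defaults to [replay_pose()].
#' @param device Optional feedback device from [mock_device()]; when given,
#'   every persisted trigger is dispatched.
#' @param mode Trial mode, `"baseline"` or `"training"` (controls water).
#' @param persist_start_ms Session time (ms) at which persistence begins.
#' @param processing_delay_ms Simulated pose+decision latency added to the
#'   second frame time to form the decision time stamp.
#' @param persistence_delay_ms Simulated cost of labeled-frame persistence.
#'   Persistence runs on its own logical task and must never block feedback:
#'   dispatch time stamps are computed before any persistence work, so this
#'   delay is accounted in the persistence log only. Exposed so the
#'   asynchrony contract is testable.
#' @param ledger A drop ledger from [new_drop_ledger()].
#' @return A list with `decisions` (one row per evaluated pair), `events`
#'   (persisted triggers), `feedback` (dispatched feedback events), `state`,
#'   and `ledger`.
#' @export
run_engine <- function(source, config = criterion_config(),
                       backend = replay_pose, device = NULL,
                       mode = c("training", "baseline"),
                       persist_start_ms = 0, processing_delay_ms = 30,
                       persistence_delay_ms = 0,
                       ledger = new_drop_ledger()) {
  mode <- match.arg(mode)
  cap <- 4096L
  out <- list(
    pair_index = integer(cap), second_frame = integer(cap),
    frame_time_ms = numeric(cap), decision_time_ms = numeric(cap),
    dispatch_time_ms = numeric(cap), decision = character(cap),
    reason = character(cap), dy_left = numeric(cap), dy_right = numeric(cap),
    confidence = numeric(cap), buffered = logical(cap),
    non_adjacent = logical(cap), persist_done_ms = numeric(cap)
  )
  grow <- function(o, cap2) {
    for (nm in names(o)) o[[nm]] <- c(o[[nm]], o[[nm]][0][seq_len(cap2)])
    o
  }
  feedback <- list()
  state <- engine_state()
  k <- 0L
  repeat {
    pr <- next_pair(source, ledger)
    if (is.null(pr)) break
    k <- k + 1L
    if (k > cap) { out <- grow(out, cap); cap <- 2L * cap }
    p1 <- backend(pr$first)
    p2 <- backend(pr$second)
    d <- paw_displacement(p1, p2, pair_index = k,
                          second_frame_time = pr$second$acquisition_time,
                          confidence_aggregate = config$confidence_aggregate,
                          confidence_frames = config$confidence_frames)
    buffered <- pr$second$acquisition_time < persist_start_ms
    dec <- evaluate_criterion(d, config, state)
    decision_time <- NA_real_
    dispatch_time <- NA_real_
    if (!buffered && dec$decision == "TRIGGER") {
      state <- update_refractory(state, dec, d$second_frame_time)
      decision_time <- d$second_frame_time + processing_delay_ms
      if (!is.null(device)) {
        fb <- dispatch_feedback(device, decision_time, mode, config)
        dispatch_time <- fb$dispatch_time
        feedback[[length(feedback) + 1L]] <- fb
      } else {
        dispatch_time <- decision_time
      }
    }
    out$pair_index[k] <- k
    out$second_frame[k] <- pr$second$index
    out$frame_time_ms[k] <- pr$second$acquisition_time
    out$decision_time_ms[k] <- decision_time
    out$dispatch_time_ms[k] <- dispatch_time
    out$decision[k] <- dec$decision
    out$reason[k] <- if (is.na(dec$reason)) NA_character_ else dec$reason
    out$dy_left[k] <- d$dy_left
    out$dy_right[k] <- d$dy_right
    out$confidence[k] <- d$confidence
    out$buffered[k] <- buffered
    out$non_adjacent[k] <- pr$non_adjacent
    # labeled-frame persistence completes asynchronously, after dispatch
    out$persist_done_ms[k] <- if (buffered) NA_real_ else
      pr$second$acquisition_time + processing_delay_ms + persistence_delay_ms
  }
  decisions <- as_tibble(lapply(out, function(v) v[seq_len(k)]))
  events <- decisions[decisions$decision == "TRIGGER" & !decisions$buffered, ]
  list(decisions = decisions, events = events,
       feedback = bind_rows(feedback), state = state, ledger = ledger)
}
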