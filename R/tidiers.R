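#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trial record into its event table
#'
#' @param x A `trial_record`.
#' @param ... Unused.
#' @return The persisted trigger events as a tibble, with identifying
#'   columns prepended.
#' @method tidy trial_record
#' @export
tidy.trial_record <- function(x, ...) {
  ev <- x$events
  dplyr::bind_cols(tibble(mouse = rep(x$mouse, nrow(ev)),
                          day = rep(x$day, nrow(ev)),
                          trial = rep(x$trial, nrow(ev)),
                          mode = rep(x$mode, nrow(ev))), ev)
}

#' One-row summary of a trial record
#'
#' @param x A `trial_record`.
#' @param ... Unused.
#' @return A one-row tibble: identifiers, trigger count, feedback count,
#'   frame accounting, mean output rate and mean time-stamp latency.
#' @method glance trial_record
#' @export
glance.trial_record <- function(x, ...) {
  lat <- timestamp_latency(x)
  tibble(mouse = x$mouse, day = x$day, trial = x$trial, mode = x$mode,
         n_triggers = nrow(x$events), n_feedback = nrow(x$feedback),
         emitted = x$frame_stats$emitted,
         processed = x$frame_stats$processed,
         dropped = x$frame_stats$dropped,
         mean_output_rate_hz = x$frame_stats$mean_output_rate_hz,
         mean_latency_ms = lat$mean)
}

#' Tidy an estimation result
#'
#' @param x An `estimation_result` from [bootstrap_mean_difference()].
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `conf.low`, `conf.high`, `n`,
#'   `n_resamples`, `ci_level`, `method`, `seed`.
#' @method tidy estimation_result
#' @export
tidy.estimation_result <- function(x, ...) {
  tibble(estimate = x$mean_difference, conf.low = x$ci_low,
         conf.high = x$ci_high, n = x$n, n_resamples = x$n_resamples,
         ci_level = x$ci_level, method = x$method, seed = x$seed)
}

#' Tidy a latency result
#'
#' @param x A `latency_result`.
#' @param ... Unused.
#' @return A tibble with one row per event latency.
#' @method tidy latency_result
#' @export
tidy.latency_result <- function(x, ...) {
  tibble(event = seq_along(x$latencies), latency_ms = x$latencies,
         method = x$method)
}

#' One-row summary of a latency result
#' @param x A `latency_result`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n`, `mean_ms`, `sd_ms`,
#'   `n_flagged`, `n_unmatched`.
#' @method glance latency_result
#' @export
glance.latency_result <- function(x, ...) {
  tibble(method = x$method, n = length(x$latencies), mean_ms = x$mean,
         sd_ms = x$sd, n_flagged = length(x$flagged),
         n_unmatched = length(x$unmatched %||% integer()))
}
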