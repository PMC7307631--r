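#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_vline geom_hline
#'   geom_col geom_errorbar geom_pointrange labs facet_wrap theme_minimal
#'   autoplot position_dodge
#' @export
ggplot2::autoplot

#' Plot paw displacement traces with trigger marks
#'
#' Per-pair absolute vertical displacement of each paw across a trial, with
#' vertical marks at every persisted trigger — the standard single-trial
#' view of selective triggering.
#'
#' @param object A `trial_record`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trial_record
#' @export
autoplot.trial_record <- function(object, ...) {
  dec <- object$decisions
  long <- tidyr::pivot_longer(
    dec[, c("frame_time_ms", "dy_left", "dy_right")],
    cols = c("dy_left", "dy_right"), names_to = "paw",
    values_to = "dy", names_prefix = "dy_")
  ggplot(long, aes(x = .data$frame_time_ms / 1000, y = .data$dy,
                   colour = .data$paw)) +
    geom_line(alpha = 0.8) +
    geom_vline(xintercept = object$events$frame_time_ms / 1000,
               linetype = "dotted", colour = "grey40") +
    geom_hline(yintercept = object$criterion$min_left,
               linetype = "dashed", colour = "grey60") +
    labs(x = "trial time (s)", y = "|dy| per frame pair (px)",
         colour = "paw",
         title = sprintf("%s day %d trial %d (%s): %d trigger(s)",
                         object$mouse, object$day, object$trial,
                         object$mode, nrow(object$events))) +
    theme_minimal()
}

#' Plot an LED intensity trace with threshold and detections
#'
#' @param object An `led_trace`.
#' @param k_sd Threshold criterion in baseline SDs.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot led_trace
#' @export
autoplot.led_trace <- function(object, k_sd = 3, ...) {
  onsets <- detect_flashes(object, k_sd = k_sd)
  df <- tibble(frame = seq_along(object$intensity),
               intensity = object$intensity)
  ggplot(df, aes(x = .data$frame, y = .data$intensity)) +
    geom_line(colour = "grey30") +
    geom_hline(yintercept = object$baseline_mean + k_sd * object$baseline_sd,
               linetype = "dashed", colour = "red") +
    geom_vline(xintercept = object$skip_frames, linetype = "dotted") +
    geom_point(data = df[onsets, ], colour = "red", size = 2) +
    labs(x = "frame", y = "ROI mean intensity",
         title = sprintf("%d flash onset(s) detected", length(onsets))) +
    theme_minimal()
}

#' Plot a bootstrap estimation result
#'
#' Mean difference with its bootstrapped confidence interval, the
#' estimation-statistics view of a paired contrast.
#'
#' @param object An `estimation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot estimation_result
#' @export
autoplot.estimation_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = "mean difference", y = .data$estimate)) +
    geom_pointrange(aes(ymin = .data$conf.low, ymax = .data$conf.high)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    labs(x = NULL, y = "triggers / trial",
         title = sprintf("%g%% %s bootstrap CI (B = %d)",
                         100 * object$ci_level, toupper(object$method),
                         object$n_resamples)) +
    theme_minimal()
}

#' Learning-curve plot of trigger counts
#'
#' Mean triggers per trial by day and trial mode with standard-error bars —
#' the summary view of a multi-day reinforcement experiment.
#'
#' @param counts Output of [count_triggers()].
#' @return A ggplot.
#' @export
plot_learning_curve <- function(counts) {
  sum_df <- counts |>
    group_by(.data$day, .data$mode) |>
    summarise(mean = mean(.data$n_triggers),
              sem = sd(.data$n_triggers) / sqrt(dplyr::n()),
              .groups = "drop")
  ggplot(sum_df, aes(x = factor(.data$day), y = .data$mean,
                     fill = .data$mode)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem),
                  position = position_dodge(width = 0.8), width = 0.25) +
    labs(x = "day", y = "mean triggers / trial", fill = "trial type") +
    theme_minimal()
}

#' Estimation table plot across days
#'
#' @param est_table Output of [estimation_by_day()].
#' @return A ggplot of the day-wise mean differences and CIs.
#' @export
plot_estimation_by_day <- function(est_table) {
  ggplot(est_table, aes(x = factor(.data$day), y = .data$mean_difference)) +
    geom_pointrange(aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    labs(x = "day", y = "mean difference (triggers / trial)",
         title = unique(est_table$contrast)) +
    theme_minimal()
}
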