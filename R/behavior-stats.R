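#' Tabulate trigger counts per trial
#'
#' One row per trial with the number of criterion-satisfying triggers (left
#' paw moved >= the minimum threshold while the right paw stayed within its
#' limit), keyed by mouse, day and trial mode — the raw material for the
#' learning-curve analyses.
#'
#' @param records A `trial_collection` (QC-passed).
#' @return A tibble `mouse`, `day`, `mode`, `trial`, `n_triggers`.
#' @export
count_triggers <- function(records) {
  bind_rows(lapply(records, function(r) {
    tibble(mouse = r$mouse, day = r$day, mode = r$mode, trial = r$trial,
           n_triggers = nrow(r$events))
  }))
}

#' Per-(mouse, day, mode) mean trigger counts
#'
#' @param counts Output of [count_triggers()].
#' @return A tibble with one row per cell and the per-mouse mean count.
#' @export
mean_trigger_counts <- function(counts) {
  counts |>
    group_by(.data$mouse, .data$day, .data$mode) |>
    summarise(mean_triggers = mean(.data$n_triggers), n_trials = dplyr::n(),
              .groups = "drop")
}

#' Count contralateral movements immediately after triggers
#'
#' Selectivity check: for each successful left-paw trigger, inspect the
#' immediately following frame pair and count how often the right paw moved
#' more than `threshold` pixels. Events whose pair is the last of the trace
#' cannot be followed up and are skipped (reported in `n_skipped`).
#'
#' @param trace Pose trace of the trial.
#' @param events Trigger events of the trial (needs `pair_index`).
#' @param threshold Right-paw displacement bound, px (strictly greater
#'   counts).
#' @param criterion A [criterion_config()] (pairing/confidence conventions).
#' @return A list `n_post_trigger_contralateral`, `n_skipped`, `per_event`
#'   (logical per usable event).
#' @export
count_post_trigger_contralateral <- function(trace, events, threshold = 10,
                                             criterion = criterion_config()) {
  pt <- pair_table(trace, criterion)
  usable <- events$pair_index[events$pair_index < nrow(pt)]
  n_skipped <- nrow(events) - length(usable)
  hits <- pt$dy_right[usable + 1L] > threshold
  list(n_post_trigger_contralateral = sum(hits), n_skipped = n_skipped,
       per_event = hits)
}

#' Count per-digit vertical movements
#'
#' Per-digit analogue of the trigger count: using the same non-overlapping
#' pairing and |dy| convention as the trigger engine, counts how many pairs
#' each digit of a paw moved beyond its threshold (>= for the left paw's
#' 5 px criterion, > for the right paw's 10 px limit, following the
#' reinforcement rules).
#'
#' @param trace Pose trace of one trial.
#' @param paw `"left"` or `"right"`.
#' @param threshold Displacement threshold, px; defaults to 5 (left) or 10
#'   (right).
#' @param rule `">="` or `">"`; defaults to `">="` for left, `">"` for
#'   right.
#' @return A tibble `digit`, `n_moves`.
#' @export
count_digit_movements <- function(trace, paw = c("left", "right"),
                                  threshold = NULL, rule = NULL) {
  paw <- match.arg(paw)
  if (is.null(threshold)) threshold <- if (paw == "left") 5 else 10
  if (is.null(rule)) rule <- if (paw == "left") ">=" else ">"
  digits <- if (paw == "left") LEFT_DIGITS else RIGHT_DIGITS
  rec <- trace[!trace$dropped, , drop = FALSE]
  k <- nrow(rec) %/% 2L
  if (k == 0L) return(tibble(digit = digits, n_moves = 0L))
  i1 <- seq.int(1L, by = 2L, length.out = k)
  i2 <- i1 + 1L
  Y <- as.matrix(rec[, paste0(digits, "_y")])
  dy <- abs(Y[i2, , drop = FALSE] - Y[i1, , drop = FALSE])
  cmp <- if (rule == ">=") `>=` else `>`
  tibble(digit = digits, n_moves = as.integer(colSums(cmp(dy, threshold))))
}

#' Paired t tests with Bonferroni correction across condition cells
#'
#' Compares per-mouse mean trigger counts between pairs of (day, mode)
#' cells — e.g. each training day against training day 1, or training
#' against baseline within each day — with paired-sample t tests and a
#' Bonferroni family correction (`p_adj = min(1, p * family size)`). The
#' family is the set of comparisons passed in, unless `family_size`
#' overrides it. Zero-variance difference sets are flagged, not significant.
#'
#' @param counts Output of [count_triggers()].
#' @param comparisons Tibble with columns `day_a`, `mode_a`, `day_b`,
#'   `mode_b`, one row per comparison.
#' @param family_size Number of comparisons in the declared family.
#' @param alpha Significance level applied to adjusted p values.
#' @return A tibble with one row per comparison: `t`, `df`, `p`, `p_adj`,
#'   `significant`, `mean_difference`, `zero_variance`.
#' @export
paired_t_bonferroni <- function(counts, comparisons,
                                family_size = nrow(comparisons),
                                alpha = 0.05) {
  cell_means <- mean_trigger_counts(counts)
  one <- function(day_a, mode_a, day_b, mode_b) {
    a <- filter(cell_means, .data$day == day_a, .data$mode == mode_a)
    b <- filter(cell_means, .data$day == day_b, .data$mode == mode_b)
    joined <- dplyr::inner_join(a, b, by = "mouse",
                                suffix = c("_a", "_b"))
    missing <- setdiff(union(a$mouse, b$mouse), joined$mouse)
    if (length(missing) > 0)
      abort_input("unpaired cells: mouse %s missing from one side of (%s d%s vs %s d%s)",
                  missing[1], mode_a, day_a, mode_b, day_b)
    if (nrow(joined) < 2L)
      abort_input("need >= 2 paired mice per comparison")
    d <- joined$mean_triggers_a - joined$mean_triggers_b
    if (sd(d) == 0) {
      return(tibble(day_a = day_a, mode_a = mode_a, day_b = day_b,
                    mode_b = mode_b, n = length(d), t = NA_real_,
                    df = length(d) - 1L, p = NA_real_, p_adj = NA_real_,
                    significant = FALSE, mean_difference = mean(d),
                    zero_variance = TRUE))
    }
    tt <- t.test(joined$mean_triggers_a, joined$mean_triggers_b,
                 paired = TRUE)
    tibble(day_a = day_a, mode_a = mode_a, day_b = day_b, mode_b = mode_b,
           n = length(d), t = unname(tt$statistic),
           df = unname(tt$parameter), p = tt$p.value,
           p_adj = min(1, tt$p.value * family_size),
           significant = min(1, tt$p.value * family_size) < alpha,
           mean_difference = mean(d), zero_variance = FALSE)
  }
  purrr::pmap(comparisons[c("day_a", "mode_a", "day_b", "mode_b")], one) |>
    bind_rows()
}

#' One-way ANOVA across digits within each (day, mode) stratum
#'
#' Tests whether the per-trial movement counts differ between the four
#' digits of a paw, separately for every day-by-mode stratum. Strata with
#' fewer than two digits or fewer than two observations per digit are
#' skipped with a note.
#'
#' @param digit_counts Tibble with columns `mouse`, `day`, `mode`, `trial`,
#'   `digit`, `n_moves` (one row per digit per trial).
#' @return A tibble per stratum: `day`, `mode`, `F`, `df_between`,
#'   `df_within`, `p`, `note`.
#' @export
anova_digits <- function(digit_counts) {
  strata <- dplyr::distinct(digit_counts, .data$day, .data$mode)
  purrr::pmap(strata, function(day, mode) {
    dat <- digit_counts[digit_counts$day == day & digit_counts$mode == mode, ]
    tab <- table(dat$digit)
    if (length(tab) < 2L || any(tab < 2L)) {
      return(tibble(day = day, mode = mode, F = NA_real_,
                    df_between = NA_integer_, df_within = NA_integer_,
                    p = NA_real_, note = "skipped: insufficient data"))
    }
    fit <- aov(n_moves ~ factor(digit), data = dat)
    s <- summary(fit)[[1]]
    tibble(day = day, mode = mode, F = s[["F value"]][1],
           df_between = s[["Df"]][1], df_within = s[["Df"]][2],
           p = s[["Pr(>F)"]][1], note = NA_character_)
  }) |> bind_rows()
}

#' Bootstrap estimation of a paired mean difference
#'
#' Estimation-statistics analogue of the paired t test: the mean of the
#' per-mouse paired differences, with a bootstrapped confidence interval
#' obtained by resampling mice with replacement. The default interval is
#' bias-corrected and accelerated (BCa), matching the estimation-statistics
#' package family used for this analysis; a plain percentile interval is
#' available as a fallback. Deterministic under a fixed seed.
#'
#' @param pairs Tibble with columns `a` and `b` (one row per mouse), or a
#'   numeric vector of paired differences.
#' @param n_resamples Number of bootstrap resamples (>= 100).
#' @param seed Integer seed (mandatory for reporting).
#' @param ci_level Confidence level (default 0.95).
#' @param method `"bca"` or `"percentile"`.
#' @return An `estimation_result`: `mean_difference`, `ci_low`, `ci_high`,
#'   `n`, `n_resamples`, `ci_level`, `method`, `seed`.
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(a = rnorm(7, 12), b = rnorm(7, 2))
#' bootstrap_mean_difference(d, n_resamples = 1000, seed = 42)
bootstrap_mean_difference <- function(pairs, n_resamples = 5000, seed,
                                      ci_level = 0.95,
                                      method = c("bca", "percentile")) {
  method <- match.arg(method)
  if (missing(seed)) abort_config("a seed is required for bootstrap reports")
  if (n_resamples < 100)
    abort_config("n_resamples must be >= 100 (got %d)", n_resamples)
  d <- if (is.data.frame(pairs)) {
    if (!all(c("a", "b") %in% names(pairs)))
      abort_input("`pairs` needs columns a and b")
    pairs$a - pairs$b
  } else as.numeric(pairs)
  n <- length(d)
  if (n < 2L) abort_input("need >= 2 pairs, got %d", n)
  obs <- mean(d)

  if (stats::var(d) == 0) {
    return(new_estimation_result(obs, obs, obs, n, n_resamples, ci_level,
                                 method, seed))
  }

  alpha <- (1 - ci_level) / 2
  boot_means <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                  nrow = n_resamples)
    rowMeans(matrix(d[idx], nrow = n_resamples))
  })

  if (method == "percentile") {
    ci <- unname(quantile(boot_means, c(alpha, 1 - alpha), type = 7))
  } else {
    # BCa: bias correction from the bootstrap distribution, acceleration
    # from the jackknife
    prop <- mean(boot_means < obs) + 0.5 * mean(boot_means == obs)
    prop <- min(max(prop, 1 / (n_resamples + 1)),
                n_resamples / (n_resamples + 1))
    z0 <- qnorm(prop)
    jack <- vapply(seq_len(n), function(i) mean(d[-i]), numeric(1))
    jm <- mean(jack) - jack
    denom <- 6 * sum(jm^2)^1.5
    a <- if (denom == 0) 0 else sum(jm^3) / denom
    zlo <- qnorm(alpha)
    zhi <- qnorm(1 - alpha)
    a1 <- pnorm(z0 + (z0 + zlo) / (1 - a * (z0 + zlo)))
    a2 <- pnorm(z0 + (z0 + zhi) / (1 - a * (z0 + zhi)))
    ci <- unname(quantile(boot_means, c(a1, a2), type = 7))
  }
  new_estimation_result(obs, ci[1], ci[2], n, n_resamples, ci_level, method,
                        seed)
}

new_estimation_result <- function(mean_difference, ci_low, ci_high, n,
                                  n_resamples, ci_level, method, seed) {
  structure(list(mean_difference = mean_difference,
                 ci_low = min(ci_low, mean_difference),
                 ci_high = max(ci_high, mean_difference),
                 n = n, n_resamples = as.integer(n_resamples),
                 ci_level = ci_level, method = method,
                 seed = as.integer(seed)),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result> mean difference %.3f, %g%% %s CI [%.3f, %.3f] (n=%d, B=%d, seed %d)\n",
              x$mean_difference, 100 * x$ci_level, toupper(x$method),
              x$ci_low, x$ci_high, x$n, x$n_resamples, x$seed))
  invisible(x)
}

#' Bootstrap estimation table across days
#'
#' Applies [bootstrap_mean_difference()] to the standard day-wise contrasts
#' of the reinforcement analysis: training minus baseline within each day,
#' and each later day minus day 1 within a mode.
#'
#' @param counts Output of [count_triggers()].
#' @param contrast `"training_vs_baseline"`, `"training_vs_day1"` or
#'   `"baseline_vs_day1"`.
#' @param n_resamples,seed,ci_level,method Passed to
#'   [bootstrap_mean_difference()]; per-row seeds are derived from `seed`.
#' @return A tibble with one row per contrast cell and the estimation
#'   columns.
#' @export
estimation_by_day <- function(counts,
                              contrast = c("training_vs_baseline",
                                           "training_vs_day1",
                                           "baseline_vs_day1"),
                              n_resamples = 5000, seed = 1L,
                              ci_level = 0.95, method = "bca") {
  contrast <- match.arg(contrast)
  cm <- mean_trigger_counts(counts)
  days <- sort(unique(cm$day))
  rows <- if (contrast == "training_vs_baseline") {
    lapply(days, function(dd) list(day = dd,
      a = filter(cm, .data$day == dd, .data$mode == "training"),
      b = filter(cm, .data$day == dd, .data$mode == "baseline")))
  } else {
    md <- if (contrast == "training_vs_day1") "training" else "baseline"
    lapply(setdiff(days, min(days)), function(dd) list(day = dd,
      a = filter(cm, .data$day == dd, .data$mode == md),
      b = filter(cm, .data$day == min(days), .data$mode == md)))
  }
  purrr::imap(rows, function(r, i) {
    joined <- dplyr::inner_join(r$a, r$b, by = "mouse",
                                suffix = c("_a", "_b"))
    est <- bootstrap_mean_difference(
      tibble(a = joined$mean_triggers_a, b = joined$mean_triggers_b),
      n_resamples = n_resamples, seed = seed + i, ci_level = ci_level,
      method = method)
    tibble(contrast = contrast, day = r$day,
           mean_difference = est$mean_difference,
           ci_low = est$ci_low, ci_high = est$ci_high, n = est$n,
           excludes_zero = est$ci_low > 0 | est$ci_high < 0)
  }) |> bind_rows()
}
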