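# Fixture factories: small, fast synthetic sessions built in code.

# a perfectly quiet session (no reaches, no noise, no drops)
quiet_script <- function(duration = 4, frame_rate = 50, seed = 1, ...) {
  motion_script(duration = duration, frame_rate = frame_rate,
                drop_probability = 0, baseline_jitter_sd = 0,
                timestamp_jitter_sd = 0, seed = seed, ...)
}

# left reaches at given onsets, otherwise clean
reach_script <- function(onsets, duration = 6, frame_rate = 50,
                         amplitude = 20, paw = "left", seed = 1, ...) {
  motion_script(duration = duration, frame_rate = frame_rate,
                reach_events = reach_schedule(onsets, paw = paw,
                                              amplitude = amplitude),
                drop_probability = 0, baseline_jitter_sd = 0,
                timestamp_jitter_sd = 0, seed = seed, ...)
}

# a randomized session drawing rates, amplitudes, drops, grooming and jitter;
# used for engine-vs-oracle equivalence sweeps
random_session_script <- function(seed) {
  withr::with_seed(seed, {
    duration <- runif(1, 8, 14)
    frame_rate <- runif(1, 40, 120)
    n_left <- rpois(1, 6)
    n_right <- rpois(1, 3)
    onsets <- sort(runif(n_left + n_right, 0.5, duration - 0.5))
    paw <- sample(rep(c("left", "right"),
                      c(n_left, n_right))[seq_along(onsets)])
    groom <- if (runif(1) < 0.5) {
      s <- runif(1, 1, duration - 2)
      tibble::tibble(start = s, end = s + runif(1, 0.5, 1.5))
    } else NULL
    motion_script(
      duration = duration, frame_rate = frame_rate,
      reach_events = if (length(onsets) > 0)
        reach_schedule(onsets, paw = paw,
                       amplitude = runif(length(onsets), 4, 60),
                       rise = runif(length(onsets), 0.05, 0.2)) else NULL,
      grooming_intervals = groom,
      drop_probability = runif(1, 0, 0.3),
      baseline_jitter_sd = runif(1, 0, 1.5),
      timestamp_jitter_sd = runif(1, 0, 5),
      seed = seed)
  })
}

# minimal hand-built trace: given per-frame left/right mean y (all four
# digits move together), constant confidence
toy_trace <- function(y_left, y_right = rep(100, length(y_left)),
                      t_ms = NULL, lik = 1, dropped = NULL) {
  n <- length(y_left)
  if (is.null(t_ms)) t_ms <- (seq_len(n) - 1) * 10
  if (is.null(dropped)) dropped <- rep(FALSE, n)
  tr <- tibble::tibble(frame = seq_len(n), t_ms = t_ms, dropped = dropped)
  for (d in c("L1", "L2", "L3", "L4")) {
    tr[[paste0(d, "_x")]] <- 50
    tr[[paste0(d, "_y")]] <- y_left
    tr[[paste0(d, "_lik")]] <- lik
  }
  for (d in c("R1", "R2", "R3", "R4")) {
    tr[[paste0(d, "_x")]] <- 200
    tr[[paste0(d, "_y")]] <- y_right
    tr[[paste0(d, "_lik")]] <- lik
  }
  tr[tr$dropped, -(1:3)] <- NA_real_
  tr
}

# simple 2-D Gaussian blur used to stress the marker-centroid estimator
blur_image <- function(img, sigma = 1) {
  r <- ceiling(3 * sigma)
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(m, n) m[pmin(pmax(seq_len(nrow(m) + 2 * n) - n, 1),
                               nrow(m)), , drop = FALSE]
  conv_rows <- function(m) {
    p <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(nrow(m)))
      out[i, ] <- colSums(p[i:(i + 2 * r), , drop = FALSE] * k)
    out
  }
  t(conv_rows(t(conv_rows(img))))
}

digit_y_cols <- paste0(c("L1", "L2", "L3", "L4", "R1", "R2", "R3", "R4"), "_y")
digit_x_cols <- paste0(c("L1", "L2", "L3", "L4", "R1", "R2", "R3", "R4"), "_x")
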