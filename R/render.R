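#' LED region of interest
#'
#' The feedback LED sits on the head-fixing pole above the animal and is
#' rendered inside a fixed corner region of the frame. By default the ROI is
#' a 24x24 px square in the top-right corner. Coordinates are 1-based pixel
#' indices, top-left origin.
#'
#' @param width,height Frame size, pixels.
#' @param size ROI edge length, pixels; by default 24 px, shrunk to a
#'   quarter of the frame edge on very small frames so the ROI never
#'   overlaps the paw region.
#' @return A list `(x0, y0, w, h)` of 1-based inclusive pixel extents.
#' @export
led_roi <- function(width = 256, height = 256,
                    size = max(12, min(24, floor(width / 4)))) {
  size <- min(size, width, height)
  list(x0 = width - size + 1L, y0 = 1L, w = as.integer(size),
       h = as.integer(size))
}

roi_cols <- function(roi) seq(roi$x0, roi$x0 + roi$w - 1L)
roi_rows <- function(roi) seq(roi$y0, roi$y0 + roi$h - 1L)

#' Render a pose trace into an 8-bit frame sequence
#'
#' Produces the synthetic video a session would have recorded: a constant
#' background, a bright square marker at each digit-tip position, and a
#' bright disc inside the LED ROI during flash frames. Dropped frames are
#' rendered as all-zero placeholders so frame indices stay aligned with the
#' trace.
#'
#' @param trace A pose trace tibble from [generate_pose_trace()] (or the
#'   noise-free `truth$positions` table).
#' @param led_onsets Frame indices at which an LED flash begins.
#' @param led_pulse_frames Flash length, frames.
#' @param width,height Frame size, pixels (>= 64).
#' @param background Background intensity (0-255).
#' @param marker_intensity Marker intensity (0-255).
#' @param marker_radius Marker half-width, pixels.
#' @param noise_sd Per-pixel Gaussian noise SD, intensity units (0 = clean).
#' @param roi LED region of interest, from [led_roi()].
#' @param seed Seed for the pixel noise.
#' @return A `frame_stack`: list with `frames` (integer array
#'   `n x height x width`), `roi`, `led_onsets`, `led_pulse_frames`, `t_ms`.
#' @export
render_frames <- function(trace,
                          led_onsets = integer(),
                          led_pulse_frames = 14L,
                          width = 256, height = 256,
                          background = 20,
                          marker_intensity = 255,
                          marker_radius = 2L,
                          noise_sd = 0,
                          roi = led_roi(width, height),
                          seed = 1L) {
  if (width < 64 || height < 64)
    abort_input("render resolution must be at least 64x64 px")
  n <- nrow(trace)
  xs <- as.matrix(trace[, digit_cols("x")])
  ys <- as.matrix(trace[, digit_cols("y")])
  dropped <- if ("dropped" %in% names(trace)) trace$dropped else rep(FALSE, n)

  live <- which(!dropped)
  bad <- live[rowSums(xs[live, , drop = FALSE] < 1 |
                      xs[live, , drop = FALSE] > width |
                      ys[live, , drop = FALSE] < 1 |
                      ys[live, , drop = FALSE] > height,
                      na.rm = TRUE) > 0]
  if (length(bad) > 0)
    abort_input("keypoint outside the %dx%d frame at frame %d",
                width, height, bad[1])

  flash <- rep(FALSE, n)
  for (on in led_onsets) {
    idx <- seq(on, min(n, on + led_pulse_frames - 1L))
    flash[idx] <- TRUE
  }

  # LED disc mask within the full frame
  cx <- roi$x0 + (roi$w - 1) / 2
  cy <- roi$y0 + (roi$h - 1) / 2
  led_r <- max(2, floor(min(roi$w, roi$h) / 3))
  colg <- matrix(seq_len(width), height, width, byrow = TRUE)
  rowg <- matrix(seq_len(height), height, width)
  led_mask <- (colg - cx)^2 + (rowg - cy)^2 <= led_r^2

  frames <- array(0L, dim = c(n, height, width))
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      if (dropped[i]) next
      img <- matrix(background, height, width)
      for (d in 1:8) {
        px <- round(xs[i, d]); py <- round(ys[i, d])
        rr <- max(1, py - marker_radius):min(height, py + marker_radius)
        cc <- max(1, px - marker_radius):min(width, px + marker_radius)
        img[rr, cc] <- marker_intensity
      }
      if (flash[i]) img[led_mask] <- marker_intensity
      if (noise_sd > 0)
        img <- img + matrix(rnorm(height * width, 0, noise_sd), height, width)
      frames[i, , ] <- as.integer(pmin(pmax(round(img), 0), 255))
    }
  })

  structure(list(frames = frames, roi = roi, led_onsets = as.integer(led_onsets),
                 led_pulse_frames = as.integer(led_pulse_frames),
                 t_ms = trace$t_ms, dropped = dropped,
                 width = as.integer(width), height = as.integer(height)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames, %dx%d px, %d LED flash(es)\n",
              dim(x$frames)[1], x$width, x$height, length(x$led_onsets)))
  invisible(x)
}

#' Mean ROI intensity per frame
#'
#' Extracts the per-frame mean pixel intensity inside the LED region of
#' interest — the raw signal from which LED flash onsets are detected.
#' Dropped (placeholder) frames yield `NA`.
#'
#' @param stack A `frame_stack` from [render_frames()].
#' @param roi Region of interest; defaults to the stack's own.
#' @return A numeric vector of length `n_frames`.
#' @export
roi_intensity <- function(stack, roi = stack$roi) {
  n <- dim(stack$frames)[1]
  out <- vapply(seq_len(n), function(i) {
    mean(stack$frames[i, roi_rows(roi), roi_cols(roi)])
  }, numeric(1))
  out[stack$dropped] <- NA_real_
  out
}
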