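#' Estimate the 8 digit-tip keypoints from a rendered frame
#'
#' Dependency-free oracle pose estimator for synthetic frames: bright pixels
#' (excluding the LED region of interest) are grouped into connected blobs
#' by single-linkage clustering and each blob's intensity centroid becomes a
#' keypoint. Labels are assigned geometrically — the four leftmost centroids
#' are the left-paw digits, the rest the right paw, ordered by x within each
#' paw. Confidence is 1 when exactly 8 markers are found, 0 otherwise (the
#' missing keypoints are returned as `NA`).
#'
#' @param image A `height x width` intensity matrix.
#' @param roi LED region of interest to mask out, from [led_roi()]; `NULL`
#'   to search the whole frame.
#' @param threshold Intensity above which a pixel belongs to a marker. The
#'   default (background + half the marker contrast, assuming 20/255) suits
#'   frames from [render_frames()].
#' @param merge_radius Pixel distance below which bright pixels are merged
#'   into one blob.
#' @return A `pose_estimate` tibble with columns `label`, `x`, `y`,
#'   `confidence` (8 rows, DIGITS order).
#' @export
#' @examples
#' sess <- generate_pose_trace(motion_script(duration = 0.2, frame_rate = 20,
#'   drop_probability = 0, baseline_jitter_sd = 0, timestamp_jitter_sd = 0,
#'   width = 96, height = 96, seed = 2))
#' stk <- render_frames(sess$trace, width = 96, height = 96)
#' estimate_pose(stk$frames[1, , ], roi = stk$roi)
estimate_pose <- function(image, roi = NULL, threshold = 137,
                          merge_radius = 3) {
  if (!is.matrix(image) || !is.numeric(image))
    abort_input("pose backend requires a numeric intensity matrix")
  img <- image
  if (!is.null(roi)) img[roi_rows(roi), roi_cols(roi)] <- 0

  idx <- which(img > threshold, arr.ind = TRUE)
  empty <- tibble(label = DIGITS, x = NA_real_, y = NA_real_, confidence = 0)
  class(empty) <- c("pose_estimate", class(empty))
  if (nrow(idx) == 0L) return(empty)

  pts <- tibble(x = as.numeric(idx[, "col"]), y = as.numeric(idx[, "row"]),
                w = img[idx])
  if (nrow(pts) > 1L) {
    cl <- stats::cutree(stats::hclust(stats::dist(pts[, c("x", "y")]),
                                      method = "single"), h = merge_radius)
  } else cl <- 1L
  cent <- pts |>
    mutate(blob = cl) |>
    group_by(.data$blob) |>
    summarise(x = sum(.data$x * .data$w) / sum(.data$w),
              y = sum(.data$y * .data$w) / sum(.data$w),
              size = dplyr::n(), .groups = "drop")

  if (nrow(cent) != 8L) {
    out <- empty
    k <- min(8L, nrow(cent))
    ord <- order(cent$x)[seq_len(k)]
    out$x[seq_len(k)] <- cent$x[ord]
    out$y[seq_len(k)] <- cent$y[ord]
    return(out)
  }
  cent <- arrange(cent, .data$x)
  left <- arrange(cent[1:4, ], .data$x)
  right <- arrange(cent[5:8, ], .data$x)
  out <- tibble(label = DIGITS,
                x = c(left$x, right$x),
                y = c(left$y, right$y),
                confidence = 1)
  class(out) <- c("pose_estimate", class(out))
  out
}

#' Pose estimate from a replayed trace record
#'
#' The replay backend trusts the keypoints carried by the frame record
#' (e.g. a DeepLabCut-dialect trace) instead of re-estimating them from the
#' image — the pose estimator contract without a network.
#'
#' @param record A frame record from a `frame_source`.
#' @return A `pose_estimate` tibble (`label`, `x`, `y`, `confidence`).
#' @export
replay_pose <- function(record) {
  out <- tibble(label = DIGITS, x = unname(record$x), y = unname(record$y),
                confidence = unname(record$likelihood))
  class(out) <- c("pose_estimate", class(out))
  out
}

#' Mean paw position
#'
#' The positions of the four digit tips of a paw are averaged into a single
#' paw position; it is this averaged position whose frame-to-frame change
#' drives the trigger criterion.
#'
#' @param pose A `pose_estimate` tibble (8 keypoints).
#' @param paw `"left"` or `"right"`.
#' @return Named numeric `c(x = ..., y = ...)`.
#' @export
#' @examples
#' p <- tibble::tibble(label = c("L1","L2","L3","L4","R1","R2","R3","R4"),
#'                     x = 1:8, y = c(100, 102, 98, 100, 1, 1, 1, 1),
#'                     confidence = 1)
#' mean_paw_position(p, "left")
mean_paw_position <- function(pose, paw = c("left", "right")) {
  paw <- match.arg(paw)
  labels <- if (paw == "left") LEFT_DIGITS else RIGHT_DIGITS
  rows <- pose$label %in% labels
  if (sum(rows) != 4L)
    abort_input("pose is incomplete: %d %s-paw keypoints", sum(rows), paw)
  c(x = mean(pose$x[rows]), y = mean(pose$y[rows]))
}
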