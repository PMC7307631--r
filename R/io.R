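#' Write a pose trace as a DeepLabCut-dialect CSV
#'
#' Three header rows (scorer / bodyparts / coords) followed by one row per
#' frame with x, y, likelihood columns for each bodypart, frame index in the
#' first column. Dropped frames are written as empty cells (the placeholder
#' rows by which dropped frames are counted).
#'
#' @param trace Pose trace tibble.
#' @param path Output file.
#' @param scorer Scorer name written into the first header row.
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(trace, path, scorer = "pawtrigger_synth") {
  cols <- as.vector(t(cbind(digit_cols("x"), digit_cols("y"),
                            digit_cols("lik"))))
  bodyparts <- rep(DIGITS, each = 3)
  coords <- rep(c("x", "y", "likelihood"), times = 8)
  hdr <- c(paste(c("scorer", rep(scorer, 24)), collapse = ","),
           paste(c("bodyparts", bodyparts), collapse = ","),
           paste(c("coords", coords), collapse = ","))
  mat <- as.matrix(trace[, cols])
  body <- vapply(seq_len(nrow(mat)), function(i) {
    vals <- mat[i, ]
    cells <- ifelse(is.na(vals), "", formatC(vals, format = "g", digits = 10))
    paste(c(trace$frame[i] - 1L, cells), collapse = ",")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a DeepLabCut-dialect pose CSV
#'
#' Inverse of [write_dlc_csv()]: parses the three header rows, matches the
#' bodypart/coord columns, and returns the trace in this package's wide
#' layout. Rows with empty coordinate cells become placeholder (dropped)
#' frames. Timestamps are not part of the DLC dialect; supply them
#' separately or via a sidecar (see [read_timestamps()]).
#'
#' @param path CSV file written by [write_dlc_csv()] (or DeepLabCut).
#' @param t_ms Optional per-frame timestamps, ms.
#' @return A pose trace tibble.
#' @export
read_dlc_csv <- function(path, t_ms = NULL) {
  lines <- readLines(path)
  if (length(lines) < 4L) abort_input("%s is not a DLC pose CSV", path)
  bodyparts <- strsplit(lines[2], ",")[[1]][-1]
  coords <- strsplit(lines[3], ",")[[1]][-1]
  colnames <- paste0(bodyparts, "_", ifelse(coords == "likelihood", "lik",
                                            coords))
  dat <- readr::read_csv(I(paste(lines[-(1:3)], collapse = "\n")),
                         col_names = c("frame0", colnames),
                         col_types = readr::cols(.default = "d"),
                         progress = FALSE)
  want <- as.vector(t(cbind(digit_cols("x"), digit_cols("y"),
                            digit_cols("lik"))))
  if (!all(want %in% names(dat)))
    abort_input("%s does not contain the 8 expected digit bodyparts", path)
  n <- nrow(dat)
  trace <- dplyr::bind_cols(
    tibble(frame = dat$frame0 + 1L,
           t_ms = if (is.null(t_ms)) (dat$frame0) * 0 else t_ms,
           dropped = !complete.cases(dat[, want])),
    dat[, want])
  trace
}

#' Write per-frame timestamps as a JSON sidecar
#' @param t_ms Timestamps, ms.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timestamps <- function(t_ms, path) {
  jsonlite::write_json(list(t_ms = t_ms), path, digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' Read a timestamp sidecar written by [write_timestamps()]
#' @param path JSON file.
#' @return Numeric vector of timestamps, ms.
#' @export
read_timestamps <- function(path) {
  as.numeric(jsonlite::read_json(path, simplifyVector = TRUE)$t_ms)
}

#' Serialize a trial record to JSON
#'
#' Round-trip persistence for [run_trial()] output: all event, decision,
#' feedback and accounting tables plus the config snapshots. Reloading with
#' [read_trial_json()] reproduces every downstream statistic unchanged.
#'
#' @param record A `trial_record`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trial_json <- function(record, path) {
  payload <- list(
    mouse = record$mouse, day = record$day, trial = record$trial,
    mode = record$mode, cue_on = record$cue_on,
    events = record$events, decisions = record$decisions,
    feedback = record$feedback, frame_stats = record$frame_stats,
    throughput = record$throughput, device_timeline = record$device_timeline,
    config = unclass(record$config), criterion = unclass(record$criterion)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Reload a trial record written by [write_trial_json()]
#' @param path JSON file.
#' @return A `trial_record`.
#' @export
read_trial_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  tabs <- c("events", "decisions", "feedback", "frame_stats", "throughput",
            "device_timeline")
  for (nm in tabs) p[[nm]] <- as_tibble(p[[nm]])
  p$config <- structure(
    modifyList(p$config, list(resolution = as.integer(p$config$resolution))),
    class = "session_config")
  p$criterion <- structure(p$criterion, class = "criterion_config")
  p$day <- as.integer(p$day)
  p$trial <- as.integer(p$trial)
  structure(p, class = "trial_record")
}

#' Write a frame stack as a multi-page TIFF
#'
#' @param stack A `frame_stack` from [render_frames()].
#' @param path Output `.tif` file.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort_input("the 'tiff' package is required to write TIFF stacks")
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(i) stack$frames[i, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}
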