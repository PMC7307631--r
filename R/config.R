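#' Load and validate a YAML configuration file
#'
#' A configuration file has up to three sections — `session`, `criterion`
#' and `analysis` — whose keys mirror the fields of [session_config()],
#' [criterion_config()] and the analysis settings (`bootstrap_resamples`,
#' `ci_level`, `bootstrap_method`, `qc_max_latency_ms`, `seed`). Unknown
#' sections or keys are rejected, and every nested invariant is checked by
#' the constructors, so an invalid file fails with an error naming the field
#' and constraint.
#'
#' @param path YAML file.
#' @return A list `(session, criterion, analysis)` of validated configs.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_input("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_sections <- c("session", "criterion", "analysis")
  extra <- setdiff(names(raw), known_sections)
  if (length(extra) > 0)
    abort_config("unknown config section(s): %s", paste(extra, collapse = ", "))

  check_keys <- function(given, allowed, section) {
    bad <- setdiff(names(given), allowed)
    if (length(bad) > 0)
      abort_config("unknown key(s) in `%s`: %s", section,
                   paste(bad, collapse = ", "))
  }
  ses <- raw$session %||% list()
  check_keys(ses, names(formals(session_config)), "session")
  crit <- raw$criterion %||% list()
  check_keys(crit, names(formals(criterion_config)), "criterion")
  ana_defaults <- list(bootstrap_resamples = 5000L, ci_level = 0.95,
                       bootstrap_method = "bca", qc_max_latency_ms = 500,
                       seed = 1L)
  ana <- raw$analysis %||% list()
  check_keys(ana, names(ana_defaults), "analysis")
  ana <- modifyList(ana_defaults, ana)
  if (ana$bootstrap_resamples < 100)
    abort_config("analysis.bootstrap_resamples must be >= 100")
  if (ana$ci_level <= 0 || ana$ci_level >= 1)
    abort_config("analysis.ci_level must lie in (0, 1)")
  if (!ana$bootstrap_method %in% c("bca", "percentile"))
    abort_config("analysis.bootstrap_method must be 'bca' or 'percentile'")

  list(session = do.call(session_config, ses),
       criterion = do.call(criterion_config, crit),
       analysis = ana)
}

#' Reproducibility manifest for a run
#'
#' Records everything needed to reproduce a persisted output: a hash of the
#' configuration, the seeds in play, the package version, digests of input
#' files, and wall-clock start/end times.
#'
#' @param config Configuration list (e.g. from [load_config()]).
#' @param seeds Named list/vector of seeds used.
#' @param inputs Character vector of input file paths to digest.
#' @param started,finished POSIXct wall-clock stamps.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(config, seeds = list(), inputs = character(),
                         started = Sys.time(), finished = Sys.time()) {
  digests <- vapply(inputs, function(f) {
    if (file.exists(f)) rlang::hash(readBin(f, "raw", file.size(f)))
    else NA_character_
  }, character(1))
  structure(list(
    config_hash = rlang::hash(config),
    seeds = seeds,
    package_version = as.character(utils::packageVersion("pawtrigger")),
    input_digests = as.list(digests),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' Simulate a session and persist it to disk
#'
#' Generates a synthetic session from a motion script and writes its
#' artifacts under `out_dir`: the pose trace in the DeepLabCut CSV dialect,
#' a timestamp sidecar, the ground truth as JSON, a reproducibility
#' manifest, and (optionally) the rendered frames as a multi-page TIFF.
#' The same script and seed always produce byte-identical pose CSVs.
#'
#' @param script A [motion_script()] or the path to a YAML file with
#'   motion-script fields.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional override of the script's seed.
#' @param render Also render and write frames (`frames.tif`)?
#' @param led_onsets,led_pulse_frames LED schedule for rendering.
#' @return Invisibly, a named list of the files written.
#' @export
simulate_session <- function(script, out_dir, seed = NULL, render = FALSE,
                             led_onsets = integer(), led_pulse_frames = 14L) {
  if (is.character(script)) {
    if (!file.exists(script)) abort_input("script file not found: %s", script)
    fields <- yaml::read_yaml(script)
    check <- setdiff(names(fields), names(formals(motion_script)))
    if (length(check) > 0)
      abort_config("unknown motion-script key(s): %s",
                   paste(check, collapse = ", "))
    for (nm in c("reach_events", "grooming_intervals"))
      if (!is.null(fields[[nm]])) fields[[nm]] <- bind_rows(fields[[nm]])
    script <- do.call(motion_script, fields)
  }
  if (!inherits(script, "motion_script"))
    abort_config("`script` must be a motion_script or a YAML path")
  if (!is.null(seed)) script$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  started <- Sys.time()
  sess <- generate_pose_trace(script)
  files <- list(
    pose = file.path(out_dir, "pose.csv"),
    timestamps = file.path(out_dir, "timestamps.json"),
    truth = file.path(out_dir, "truth.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_dlc_csv(sess$trace, files$pose)
  write_timestamps(sess$trace$t_ms, files$timestamps)
  jsonlite::write_json(list(
    script = unclass(script)[setdiff(names(script),
                                     c("reach_events", "grooming_intervals"))],
    reach_events = sess$truth$script$reach_events,
    grooming_intervals = sess$truth$script$grooming_intervals,
    dropped_frames = sess$truth$dropped_frames,
    reach_frames = sess$truth$reach_frames,
    led_flash_onsets = sess$truth$led_flash_onsets
  ), files$truth, digits = NA, auto_unbox = TRUE)

  if (render) {
    stack <- render_frames(sess$trace, led_onsets = led_onsets,
                           led_pulse_frames = led_pulse_frames,
                           width = script$width, height = script$height,
                           seed = script$seed)
    files$frames <- file.path(out_dir, "frames.tif")
    write_frames_tiff(stack, files$frames)
  }
  manifest <- run_manifest(unclass(script), seeds = list(seed = script$seed),
                           inputs = unlist(files[c("pose", "timestamps")]),
                           started = started)
  jsonlite::write_json(unclass(manifest), files$manifest, digits = NA,
                       auto_unbox = TRUE)
  invisible(files)
}
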