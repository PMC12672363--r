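BUNDLE_FORMAT_VERSION <- "1.0"

#' Analysis configuration with study defaults
#'
#' Nested configuration for the whole pipeline; every default equals the
#' value used online or in the published analyses (thresholds and timings in
#' the task config; 1 kHz/30 Hz filtering with 6 poles for the lever and 10
#' for photometry; 15-s initial normalization epoch; 2-min bleach bins;
#' 0.1-11 Hz spectra with 0.5-4 Hz phasic band; 1000 bootstrap resamples;
#' 5 mm/s movement-segment cutoff; 2.5 mm let-go overshoot; +/-6 ms artifact
#' blanking).
#'
#' @param ... named overrides of top-level entries.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    task = unclass(task_config()),
    lever_filter = list(fs_out = 1000, cutoff = 30, poles = 6),
    photometry_filter = list(fs_out = 1000, cutoff = 30, poles = 10),
    normalization_epoch = 15,
    bleach_bin = 120,
    psd = list(band = c(0.1, 11), nw = 3, k = 5, method = "multitaper"),
    phasic_band = c(0.5, 4),
    eta_window = c(1, 2),
    press_timepoint_pre = 0.5,
    bootstrap = list(n_boot = 1000),
    v_cut = 5,
    press_dwell = 0.05,
    letgo_overshoot = 2.5,
    blank_halfwidth = 0.006,
    alpha = 0.05)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_pv("pressvigor_error_config",
            paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "analysis_config")
}

#' Write / read an analysis configuration as JSON
#'
#' Round-trip stable; unknown keys in a file are rejected.
#'
#' @param cfg an [analysis_config()].
#' @param path JSON file path.
#' @return `read_analysis_config` returns the validated `analysis_config`.
#' @export
write_analysis_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- analysis_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop_pv("pressvigor_error_config",
            paste("unknown config keys:", paste(unknown, collapse = ", ")))
  out <- unclass(defaults)
  for (nm in names(raw)) {
    if (is.list(out[[nm]]) && is.list(raw[[nm]])) {
      bad <- setdiff(names(raw[[nm]]), names(out[[nm]]))
      if (length(bad))
        stop_pv("pressvigor_error_config",
                paste("unknown config keys:",
                      paste(paste0(nm, ".", bad), collapse = ", ")))
      out[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else out[[nm]] <- raw[[nm]]
  }
  # restore NA-able task fields and class
  out$task <- do.call(task_config, out$task[setdiff(names(out$task), character())])
  out$task <- unclass(out$task)
  structure(out, class = "analysis_config")
}

#' Assemble a session bundle
#'
#' A session bundle groups the lever trace, optional photometry trace(s),
#' the trial log and session metadata under one clock (t0 = 0).
#'
#' @param lever a [lever_trace()].
#' @param trial_log a `trial_log`.
#' @param photometry optional [photometry_trace()] or list of them.
#' @param mouse_id,session_id,session_type metadata (session_type one of
#'   "manipulation", "sham", "control").
#' @param seed generator seed if synthetic, else `NA`.
#' @param ground_truth optional ground truth (synthetic sessions).
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(lever, trial_log, photometry = NULL,
                           mouse_id, session_id,
                           session_type = c("control", "manipulation", "sham"),
                           seed = NA_integer_, ground_truth = NULL) {
  session_type <- match.arg(session_type)
  stopifnot(inherits(lever, "lever_trace"), inherits(trial_log, "trial_log"))
  if (inherits(photometry, "photometry_trace")) photometry <- list(photometry)
  structure(list(lever = lever, trial_log = trial_log,
                 photometry = photometry,
                 metadata = list(mouse_id = mouse_id, session_id = session_id,
                                 session_type = session_type,
                                 fs_lever = lever$fs,
                                 fs_photometry = if (length(photometry))
                                   photometry[[1]]$fs else NA_real_,
                                 sign_convention = "inward_positive",
                                 seed = seed,
                                 format_version = BUNDLE_FORMAT_VERSION),
                 ground_truth = ground_truth),
            class = "session_bundle")
}

#' Write a session bundle to disk
#'
#' Writes a directory with `metadata.json`, the traces as Arrow feather
#' files (columnar), the trial log as CSV tables, and any ground truth as a
#' separate CSV never read by analysis stages.
#'
#' @param bundle a [session_bundle()].
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  md <- bundle$metadata
  md$n_lever <- length(bundle$lever$position)
  md$conditions <- if (length(bundle$photometry))
    vapply(bundle$photometry, function(p) p$condition, character(1)) else list()
  jsonlite::write_json(md, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  arrow::write_feather(data.frame(position_mm = bundle$lever$position),
                       file.path(path, "lever.feather"))
  if (length(bundle$photometry)) {
    for (p in bundle$photometry)
      arrow::write_feather(data.frame(v = p$v),
                           file.path(path, sprintf("photometry_%s.feather",
                                                   p$condition)))
  }
  write.csv(bundle$trial_log$trials, file.path(path, "trials.csv"),
            row.names = FALSE)
  write.csv(bundle$trial_log$events, file.path(path, "events.csv"),
            row.names = FALSE)
  if (!is.null(bundle$ground_truth)) {
    write.csv(bundle$ground_truth$presses,
              file.path(path, "ground_truth_presses.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Validates the format version, channel presence and sample counts against
#' the metadata, applies the inward-positive sign convention (flipping traces
#' recorded inward-negative and recording the flip), and returns the bundle.
#' Distinct error conditions: `pressvigor_error_version`,
#' `pressvigor_error_missing_channel`, `pressvigor_error_fs_mismatch`.
#'
#' @param path bundle directory.
#' @return A [session_bundle()].
#' @export
read_session <- function(path) {
  mdf <- file.path(path, "metadata.json")
  if (!file.exists(mdf))
    stop_pv("pressvigor_error_missing_channel", "metadata.json not found")
  md <- jsonlite::read_json(mdf, simplifyVector = TRUE)
  if (is.null(md$format_version) ||
      !identical(as.character(md$format_version), BUNDLE_FORMAT_VERSION))
    stop_pv("pressvigor_error_version",
            sprintf("unknown bundle format version '%s'", md$format_version))
  lf <- file.path(path, "lever.feather")
  if (!file.exists(lf))
    stop_pv("pressvigor_error_missing_channel", "lever channel missing")
  lev <- arrow::read_feather(lf)
  if (!is.null(md$n_lever) && nrow(lev) != md$n_lever)
    stop_pv("pressvigor_error_fs_mismatch",
            sprintf("lever has %d samples but metadata declares %d (fs %g Hz)",
                    nrow(lev), md$n_lever, md$fs_lever))
  pos <- lev$position_mm
  flipped <- FALSE
  if (identical(md$sign_convention, "inward_negative")) {
    pos <- -pos; flipped <- TRUE
  }
  lever <- lever_trace(pos, md$fs_lever,
                       provenance = list(sign = "inward_positive",
                                         sign_flipped_on_import = flipped))
  trials <- read.csv(file.path(path, "trials.csv"))
  events <- read.csv(file.path(path, "events.csv"))
  log <- new_trial_log(trials, events)
  photometry <- NULL
  conds <- unlist(md$conditions)
  if (length(conds)) {
    photometry <- lapply(conds, function(cond) {
      pf <- file.path(path, sprintf("photometry_%s.feather", cond))
      if (!file.exists(pf))
        stop_pv("pressvigor_error_missing_channel",
                sprintf("photometry channel '%s' missing", cond))
      photometry_trace(arrow::read_feather(pf)$v, md$fs_photometry,
                       condition = cond)
    })
  }
  gt <- NULL
  gtf <- file.path(path, "ground_truth_presses.csv")
  if (file.exists(gtf)) gt <- list(presses = read.csv(gtf))
  b <- session_bundle(lever, log, photometry,
                      mouse_id = md$mouse_id, session_id = md$session_id,
                      session_type = md$session_type,
                      seed = if (is.null(md$seed)) NA_integer_ else md$seed,
                      ground_truth = gt)
  b$metadata$sign_flipped_on_import <- flipped
  b
}
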