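#' Run the full analysis pipeline over a cohort of session bundles
#'
#' Per session: lever preprocessing, press detection with let-go exclusion,
#' bootstrap vigor summaries and the within-session manipulation-vs-control
#' percent change; for sessions with photometry, the raw-signal multitaper
#' PSD with phasic excess index, initial-epoch normalization and
#' reward-aligned event-triggered average. Across sessions: a session table
#' of percent-change values and a mixed-effects manipulation-vs-sham
#' contrast per metric. All outputs are CSV/JSON under `out_dir` with a
#' manifest tying every table to the bundle ids, config hash and seed;
#' given the same seeds the outputs are byte-identical across runs. A
#' failing stage is recorded for its session and the pipeline continues.
#'
#' @param bundles list of [session_bundle()] objects (or bundle directories).
#' @param config an [analysis_config()].
#' @param out_dir report directory (created).
#' @param seed integer master seed for bootstrap resampling.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(bundles, config = analysis_config(), out_dir,
                         seed = 1L) {
  if (!length(bundles))
    stop_pv("pressvigor_error_usage", "no session bundles given")
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  write_analysis_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  task <- do.call(task_config, config$task)

  session_rows <- list(); statuses <- list(); log_lines <- character()
  for (bi in seq_along(bundles)) {
    b <- bundles[[bi]]
    if (is.character(b)) b <- read_session(b)
    sid <- paste(b$metadata$mouse_id, b$metadata$session_id, sep = "_")
    sdir <- file.path(out_dir, "sessions", sid)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    t_start <- proc.time()[["elapsed"]]
    status <- tryCatch({
      lev <- b$lever
      if (lev$fs >= 2 * config$lever_filter$fs_out) {
        lev <- preprocess_lever(lev, fs_out = config$lever_filter$fs_out,
                                cutoff = config$lever_filter$cutoff,
                                poles = config$lever_filter$poles)
      } else {
        lev <- lever_trace(butter_zerophase(lev$position, lev$fs,
                                            config$lever_filter$cutoff,
                                            config$lever_filter$poles),
                           lev$fs, t0 = lev$t0, provenance = lev$provenance)
      }
      presses <- detect_presses(lev, b$trial_log, task,
                                v_cut = config$v_cut,
                                dwell = config$press_dwell,
                                overshoot = config$letgo_overshoot)
      write.csv(as.data.frame(presses), file.path(sdir, "presses.csv"),
                row.names = FALSE)
      if (nrow(presses)) {
        sv <- session_vigor(presses, n_boot = config$bootstrap$n_boot,
                            seed = sub_seed(seed, bi))
        vig <- data.frame(
          split = c("overall", "control", "manipulation"),
          n_presses = c(sv$overall$n_presses,
                        if (is.null(sv$control)) NA else sv$control$n_presses,
                        if (is.null(sv$manipulation)) NA else sv$manipulation$n_presses),
          amplitude = c(sv$overall$amplitude$estimate,
                        if (is.null(sv$control)) NA else sv$control$amplitude$estimate,
                        if (is.null(sv$manipulation)) NA else sv$manipulation$amplitude$estimate),
          peak_velocity = c(sv$overall$peak_velocity$estimate,
                            if (is.null(sv$control)) NA else sv$control$peak_velocity$estimate,
                            if (is.null(sv$manipulation)) NA else sv$manipulation$peak_velocity$estimate))
        write.csv(vig, file.path(sdir, "vigor.csv"), row.names = FALSE)
        if (!is.null(sv$control) && !is.null(sv$manipulation)) {
          for (metric in c("amplitude", "peak_velocity")) {
            session_rows[[length(session_rows) + 1L]] <- data.frame(
              mouse_id = b$metadata$mouse_id,
              session_id = b$metadata$session_id,
              session_type = b$metadata$session_type,
              metric = metric,
              value = percent_change(sv$manipulation[[metric]]$estimate,
                                     sv$control[[metric]]$estimate),
              n_presses = sv$overall$n_presses)
          }
        }
      }
      if (length(b$photometry)) {
        for (ph in b$photometry) {
          prefix <- file.path(sdir, paste0("photometry_", ph$condition))
          if (length(ph$v) / ph$fs >= 60) {
            psd <- compute_psd(ph, band = config$psd$band, nw = config$psd$nw,
                               k = config$psd$k, method = config$psd$method)
            write.csv(as.data.frame(psd), paste0(prefix, "_psd.csv"),
                      row.names = FALSE)
            idx <- phasic_power_index(psd, band = config$phasic_band)
            writeLines(jsonlite::toJSON(list(phasic_power_index = idx),
                                        auto_unbox = TRUE, digits = NA),
                       paste0(prefix, "_phasic.json"))
          }
          norm <- normalize_to_initial(ph, epoch = config$normalization_epoch)
          rew <- b$trial_log$trials$reward_time[
            b$trial_log$trials$outcome == "rewarded"]
          if (length(rew)) {
            eta <- tryCatch(
              event_triggered_average(norm, rew, window = config$eta_window),
              pressvigor_error = function(e) NULL)
            if (!is.null(eta))
              write.csv(data.frame(time = eta$time, mean = eta$mean,
                                   sem = eta$sem),
                        paste0(prefix, "_reward_eta.csv"), row.names = FALSE)
          }
        }
      }
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    statuses[[sid]] <- status
    log_lines <- c(log_lines, sprintf("%s: %s (%.2f s)", sid, status,
                                      proc.time()[["elapsed"]] - t_start))
  }

  contrasts <- data.frame(metric = character(), estimate = numeric(),
                          se = numeric(), p = numeric(), singular = logical())
  if (length(session_rows)) {
    st <- do.call(rbind, session_rows)
    write.csv(st, file.path(out_dir, "session_table.csv"), row.names = FALSE)
    # within-mouse session number pairs the k-th session of each type
    st$session_number <- stats::ave(
      seq_len(nrow(st)), st$mouse_id, st$session_type, st$metric,
      FUN = seq_along)
    for (metric in unique(st$metric)) {
      sm <- st[st$metric == metric &
               st$session_type %in% c("manipulation", "sham"), ]
      if (length(unique(sm$mouse_id)) >= 2 &&
          length(unique(sm$session_type)) >= 2) {
        mc <- mixed_effect_contrast(sm)
        contrasts <- rbind(contrasts, data.frame(
          metric = metric, estimate = mc$estimate, se = mc$se, p = mc$p,
          singular = mc$singular))
      }
    }
  }
  write.csv(contrasts, file.path(out_dir, "cohort_contrasts.csv"),
            row.names = FALSE)

  manifest <- list(
    format_version = BUNDLE_FORMAT_VERSION,
    package_version = as.character(utils::packageVersion("pressvigor")),
    config_hash = cfg_hash,
    seed = seed,
    sessions = statuses)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(manifest)
}

#' Simulate a cohort of session bundles
#'
#' Generates matched manipulation and sham sessions for `n_mice` mice. Both
#' session types carry manipulation-flagged trials (~30% from trial 11);
#' sham sessions model no-light controls, so neither type alters press vigor
#' - matching the study's design in which any vigor difference must come
#' from the manipulation itself.
#'
#' @param n_mice number of mice.
#' @param sessions_per_type sessions of each type per mouse.
#' @param seed master seed.
#' @param session_duration session length (s).
#' @param with_photometry attach a simulated photometry trace per session.
#' @param sim_args named overrides passed to [sim_config()].
#' @return List of [session_bundle()] objects.
#' @export
simulate_cohort <- function(n_mice = 6, sessions_per_type = 3, seed = 1L,
                            session_duration = 300, with_photometry = FALSE,
                            sim_args = list()) {
  bundles <- list()
  task <- task_config()
  for (m in seq_len(n_mice)) {
    for (ty in c("manipulation", "sham")) {
      for (s in seq_len(sessions_per_type)) {
        sseed <- sub_seed(seed, m * 1000 + s * 10 + (ty == "sham"))
        args <- c(list(seed = sseed, session_duration = session_duration),
                  sim_args)
        sim <- do.call(sim_config, args)
        ses <- simulate_session(sim, task)
        ph <- NULL
        if (with_photometry) {
          ph <- simulate_photometry(sim$photometry, ses,
                                    duration = session_duration,
                                    fs = 250, seed = sseed)$trace
        }
        bundles[[length(bundles) + 1L]] <- session_bundle(
          ses$lever, ses$log, ph,
          mouse_id = sprintf("m%02d", m),
          session_id = sprintf("%s%02d", substr(ty, 1, 1), s),
          session_type = ty, seed = sseed,
          ground_truth = ses$truth)
      }
    }
  }
  bundles
}

#' Simulate a session-level contrast table
#'
#' Draws session-level percent-change values from the mixed model the
#' contrast assumes: mouse random intercepts, session-pair random
#' intercepts, residual noise, and a fixed manipulation effect. Used for
#' type-I calibration (effect 0) and effect-recovery checks.
#'
#' @param n_mice number of mice.
#' @param sessions_per_type sessions of each type per mouse.
#' @param effect fixed manipulation effect (percent-change units).
#' @param sd_mouse,sd_session,sd_noise variance components (s.d.).
#' @param seed integer seed.
#' @return Data frame with `mouse_id`, `session_number`, `session_type`,
#'   `value`.
#' @export
simulate_session_table <- function(n_mice = 6, sessions_per_type = 3,
                                   effect = 0, sd_mouse = 3, sd_session = 2,
                                   sd_noise = 4, seed = 1L) {
  with_seed(seed, {
    rows <- expand.grid(mouse_id = sprintf("m%02d", seq_len(n_mice)),
                        session_number = seq_len(sessions_per_type),
                        session_type = c("sham", "manipulation"),
                        stringsAsFactors = FALSE)
    u_mouse <- setNames(rnorm(n_mice, 0, sd_mouse),
                        sprintf("m%02d", seq_len(n_mice)))
    key <- paste(rows$mouse_id, rows$session_number)
    u_sess <- setNames(rnorm(length(unique(key)), 0, sd_session), unique(key))
    rows$value <- u_mouse[rows$mouse_id] + u_sess[key] +
      rnorm(nrow(rows), 0, sd_noise) +
      ifelse(rows$session_type == "manipulation", effect, 0)
    rows
  })
}
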