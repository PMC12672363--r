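EVENT_KINDS <- c("detection_cross", "press_cross", "reward_cross",
                 "reward_delivery", "opto_on", "opto_off")

new_trial_log <- function(trials, events) {
  structure(list(trials = trials, events = events), class = "trial_log")
}

#' @export
print.trial_log <- function(x, ...) {
  nrew <- sum(x$trials$outcome == "rewarded")
  cat(sprintf("<trial_log> %d trials (%d rewarded), %d events\n",
              nrow(x$trials), nrew, nrow(x$events)))
  invisible(x)
}

online_filter <- function(position, fs, width) {
  k <- round(width * fs)
  if (k %% 2 == 0) k <- k + 1
  if (k < 3) return(position)
  as.numeric(stats::runmed(position, k, endrule = "median"))
}

#' Score a lever trace with the online trial controller
#'
#' Re-implements the trial state machine that ran during acquisition: the
#' centered 10-ms online median filter is applied to the position trace, then
#' trials, threshold-crossing events and reward deliveries are derived sample
#' by sample. A trial starts once the lever has remained inside the detection
#' band for the hold period (and any inter-trial interval has elapsed); it
#' ends at reward delivery or at timeout. A reward requires the reward
#' threshold to be crossed strictly within `reward_window` of the detection
#' crossing that began the ongoing press. With `shift_trial` set in the
#' config, trials at or after it are scored with the raised reward threshold.
#' An incomplete trailing trial is discarded.
#'
#' @param trace a [lever_trace()] (raw, unfiltered positions in mm, inward
#'   positive).
#' @param cfg a [task_config()].
#' @return A `trial_log`: `$trials` (trial_index, start_time, end_time,
#'   outcome, reward_time, manipulation_flag) and `$events` (time, kind,
#'   trial_index). Times are seconds on the sample grid.
#' @export
run_task <- function(trace, cfg) {
  stopifnot(inherits(trace, "lever_trace"), inherits(cfg, "task_config"))
  p <- online_filter(trace$position, trace$fs, cfg$online_median_filter)
  if (length(p) < round(cfg$no_move_hold * trace$fs) + 1) {
    return(new_trial_log(empty_trials(), empty_events()))
  }
  shift_trial <- if (is.na(cfg$shift_trial)) -1L else as.integer(cfg$shift_trial)
  res <- run_task_engine(p, trace$fs,
                         cfg$detection_threshold, cfg$press_threshold,
                         cfg$reward_threshold,
                         cfg$no_move_hold, cfg$reward_window,
                         cfg$reward_delay, cfg$trial_timeout, cfg$iti,
                         shift_trial, cfg$shift_fraction)
  trials <- data.frame(trial_index = res$trial_index,
                       start_time = res$start_time,
                       end_time = res$end_time,
                       outcome = as.character(ifelse(res$rewarded == 1,
                                                     "rewarded", "timeout")),
                       reward_time = res$reward_time,
                       manipulation_flag = logical(length(res$trial_index)))
  events <- data.frame(time = res$event_time,
                       kind = EVENT_KINDS[res$event_kind],
                       trial_index = res$event_trial)
  new_trial_log(trials, events)
}

empty_trials <- function() {
  data.frame(trial_index = integer(), start_time = numeric(),
             end_time = numeric(), outcome = character(),
             reward_time = numeric(), manipulation_flag = logical())
}

empty_events <- function() {
  data.frame(time = numeric(), kind = character(), trial_index = integer())
}

#' Naive reference interpreter for the trial controller
#'
#' A deliberately simple sample-by-sample interpreter of the same task rules,
#' written as a plain R loop with explicit state variables and no shared code
#' with the compiled engine. Used as an independent oracle: on any trace,
#' [run_task()] must reproduce its output event-for-event.
#'
#' @inheritParams run_task
#' @return A `trial_log`, as for [run_task()].
#' @export
run_task_reference <- function(trace, cfg) {
  stopifnot(inherits(trace, "lever_trace"), inherits(cfg, "task_config"))
  fs <- trace$fs
  p <- online_filter(trace$position, fs, cfg$online_median_filter)
  n <- length(p)
  hold_n <- round(cfg$no_move_hold * fs)
  window_n <- round(cfg$reward_window * fs)
  delay_n <- round(cfg$reward_delay * fs)
  timeout_n <- round(cfg$trial_timeout * fs)
  iti_n <- round(cfg$iti * fs)
  det <- cfg$detection_threshold

  trials <- list(); events <- list()
  cur_events <- list()
  state <- "armed"; still <- 0L; trial <- 0L
  start_i <- NA; timeout_i <- NA; iti_end_i <- NA
  win_open <- FALSE; ws_i <- NA
  committed <- FALSE; delivery_i <- NA
  rthr <- cfg$reward_threshold

  add_ev <- function(t, kind) {
    cur_events[[length(cur_events) + 1L]] <<- list(time = t, kind = kind)
  }
  close_trial <- function(end_i, rewarded) {
    trials[[length(trials) + 1L]] <<- data.frame(
      trial_index = trial, start_time = start_i / fs, end_time = end_i / fs,
      outcome = if (rewarded) "rewarded" else "timeout",
      reward_time = if (rewarded) end_i / fs else NA_real_,
      manipulation_flag = FALSE)
    for (ev in cur_events)
      events[[length(events) + 1L]] <<- data.frame(
        time = ev$time, kind = ev$kind, trial_index = trial)
    cur_events <<- list()
  }

  i <- 1L  # R index; sample index is i - 1
  while (i <= n) {
    s <- i - 1L
    if (state == "trial") {
      if (committed && s >= delivery_i) {
        add_ev(delivery_i / fs, "reward_delivery")
        close_trial(delivery_i, TRUE)
        state <- "iti"; iti_end_i <- delivery_i + iti_n
        still <- if (abs(p[i]) < det) 1L else 0L
        i <- i + 1L; next
      }
      if (!committed && s >= timeout_i) {
        close_trial(timeout_i, FALSE)
        state <- "iti"; iti_end_i <- timeout_i + iti_n
        still <- if (abs(p[i]) < det) 1L else 0L
        i <- i + 1L; next
      }
      prev <- p[i - 1L]; cur <- p[i]; t <- s / fs
      if (prev < det && cur >= det) {
        add_ev(t, "detection_cross")
        if (!win_open) { win_open <- TRUE; ws_i <- s }
      }
      if (prev < cfg$press_threshold && cur >= cfg$press_threshold)
        add_ev(t, "press_cross")
      if (prev < rthr && cur >= rthr) {
        if (win_open && (s - ws_i) < window_n && !committed) {
          add_ev(t, "reward_cross")
          committed <- TRUE
          delivery_i <- s + delay_n
        }
      }
      if (win_open && cur < det) win_open <- FALSE
      i <- i + 1L; next
    }
    still <- if (abs(p[i]) < det) still + 1L else 0L
    if (state == "iti") {
      if (s < iti_end_i) { i <- i + 1L; next }
      state <- "armed"
    }
    if (still >= hold_n + 1L) {
      trial <- trial + 1L
      start_i <- s; timeout_i <- s + timeout_n
      state <- "trial"; win_open <- FALSE; committed <- FALSE
      rthr <- cfg$reward_threshold
      if (!is.na(cfg$shift_trial) && trial >= cfg$shift_trial)
        rthr <- cfg$reward_threshold * (1 + cfg$shift_fraction)
    }
    i <- i + 1L
  }

  trials_df <- if (length(trials)) do.call(rbind, trials) else empty_trials()
  events_df <- if (length(events)) do.call(rbind, events) else empty_events()
  new_trial_log(trials_df, events_df)
}
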