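#' Behavioral task configuration
#'
#' All thresholds and timings of the self-paced lever-press trial controller.
#' Defaults are the task as run in the study: trials start after the lever is
#' held inside a +/-0.5 mm detection band for 300 ms; a deflection counts as a
#' press above 1.7 mm and is rewarded if it crosses the reward threshold
#' (4.1 mm by default) within 0.5 s of the detection crossing; the ~5 ul water
#' reward is delivered 0.5 s after the reward crossing; trials time out after
#' 30 s and are followed by a 1-s inter-trial interval during which deflections
#' are never rewarded.
#'
#' @param detection_threshold half-width of the stillness band around rest (mm).
#' @param press_threshold minimum inward deflection that counts as a press (mm).
#' @param reward_threshold inward deflection required for reward (mm).
#' @param no_move_hold required stillness before trial start (s).
#' @param reward_window maximum detection-to-reward-crossing latency (s).
#' @param reward_delay delay from reward crossing to delivery (s).
#' @param trial_timeout maximum trial duration (s).
#' @param iti inter-trial interval (s).
#' @param online_median_filter width of the online median filter (s).
#' @param shift_trial trial index from which the reward threshold is raised
#'   (uncued mid-session threshold shift); `NA` disables the shift.
#' @param shift_fraction fractional increase of the reward threshold applied
#'   from `shift_trial` onward (0.10 = +10%).
#' @return An object of class `task_config`.
#' @seealso [run_task()], [apply_threshold_shift()]
#' @export
task_config <- function(detection_threshold = 0.5,
                        press_threshold = 1.7,
                        reward_threshold = 4.1,
                        no_move_hold = 0.300,
                        reward_window = 0.5,
                        reward_delay = 0.5,
                        trial_timeout = 30,
                        iti = 1.0,
                        online_median_filter = 0.010,
                        shift_trial = NA_integer_,
                        shift_fraction = 0.10) {
  if (!(detection_threshold > 0 && detection_threshold < press_threshold &&
        press_threshold < reward_threshold))
    stop_pv("pressvigor_error_config",
            "need 0 < detection_threshold < press_threshold < reward_threshold")
  durs <- c(no_move_hold, reward_window, reward_delay, trial_timeout, iti,
            online_median_filter)
  if (any(durs <= 0))
    stop_pv("pressvigor_error_config", "all durations must be > 0")
  if (!is.na(shift_trial) && shift_trial < 1)
    stop_pv("pressvigor_error_config", "shift_trial must be >= 1")
  if (shift_fraction <= -1)
    stop_pv("pressvigor_error_config", "shift_fraction must be > -1")
  structure(list(detection_threshold = detection_threshold,
                 press_threshold = press_threshold,
                 reward_threshold = reward_threshold,
                 no_move_hold = no_move_hold,
                 reward_window = reward_window,
                 reward_delay = reward_delay,
                 trial_timeout = trial_timeout,
                 iti = iti,
                 online_median_filter = online_median_filter,
                 shift_trial = shift_trial,
                 shift_fraction = shift_fraction),
            class = "task_config")
}

#' Arm the uncued mid-session reward-threshold shift
#'
#' Returns a copy of the configuration in which the reward threshold is
#' multiplied by `1 + shift_fraction` for every trial at or after
#' `trial_index`. The input configuration is unchanged.
#'
#' @param cfg a [task_config()].
#' @param trial_index first trial scored with the raised threshold (>= 1).
#' @param shift_fraction fractional increase (default +10%).
#' @return A modified `task_config`.
#' @export
apply_threshold_shift <- function(cfg, trial_index, shift_fraction = 0.10) {
  stopifnot(inherits(cfg, "task_config"))
  if (trial_index < 1)
    stop_pv("pressvigor_error_config", "trial_index must be >= 1")
  if (shift_fraction <= -1)
    stop_pv("pressvigor_error_config", "shift_fraction must be > -1")
  cfg$shift_trial <- as.integer(trial_index)
  cfg$shift_fraction <- shift_fraction
  cfg
}

#' Reward threshold in force on a given trial
#'
#' @param cfg a [task_config()].
#' @param trial_index trial number (1-based).
#' @return The reward threshold (mm) applied when scoring that trial.
#' @export
reward_threshold_for_trial <- function(cfg, trial_index) {
  base <- cfg$reward_threshold
  if (!is.na(cfg$shift_trial) && trial_index >= cfg$shift_trial)
    base * (1 + cfg$shift_fraction)
  else base
}
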