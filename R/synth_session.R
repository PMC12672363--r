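#' Simulate a complete lever-press session with ground truth
#'
#' Draws press times, amplitudes and peak velocities from the configured
#' distributions, synthesizes the lever-position trace (raised-cosine presses,
#' optional let-go release oscillations, postural micro-adjustments, encoder
#' noise), and scores it closed-loop with [run_task()] so reward decisions
#' follow the task rules exactly. A pseudo-random ~30% subset of trials from
#' the configured start trial is flagged as optogenetic manipulation trials
#' and given a pulse schedule. All outputs are a pure function of
#' (`sim`, `task`).
#'
#' @param sim a [sim_config()].
#' @param task a [task_config()].
#' @return A list of class `synthetic_session` with elements `lever`
#'   ([lever_trace()]), `log` (`trial_log`), and `truth` (ground truth:
#'   `$presses` with onset/amplitude/peak velocity/let-go flag,
#'   `$reward_times`, `$opto_trials`, `$pulse_times`).
#' @export
simulate_session <- function(sim, task = task_config()) {
  stopifnot(inherits(sim, "sim_config"), inherits(task, "task_config"))
  fs <- sim$fs
  n <- round(sim$session_duration * fs)

  presses <- with_seed(sub_seed(sim$seed, 1), {
    if (sim$press_rate <= 0) {
      data.frame(onset = numeric(), amplitude = numeric(),
                 peak_velocity = numeric(), has_letgo = logical())
    } else {
      mean_gap <- 1 / sim$press_rate
      if (mean_gap < sim$min_gap)
        warning("press_rate exceeds the refractory limit; inter-press gaps thinned to min_gap")
      onsets <- c(); t <- 2.0
      while (TRUE) {
        t <- t + max(sim$min_gap, rexp(1, sim$press_rate))
        if (t > sim$session_duration - 2) break
        onsets <- c(onsets, t)
      }
      k <- length(onsets)
      amp <- rlnorm(k, sim$amplitude_dist[["meanlog"]],
                    sim$amplitude_dist[["sdlog"]])
      vel <- rlnorm(k, sim$peak_velocity_dist[["meanlog"]],
                    sim$peak_velocity_dist[["sdlog"]])
      vel <- pmin(pmax(vel, 4 * amp), 40 * amp)
      letgo <- runif(k) < sim$letgo_prob
      data.frame(onset = onsets, amplitude = amp, peak_velocity = vel,
                 has_letgo = letgo)
    }
  })

  x <- numeric(n)
  t_peaks <- numeric(nrow(presses))
  if (nrow(presses)) {
    for (j in seq_len(nrow(presses))) {
      w <- simulate_press_waveform(presses$amplitude[j],
                                   presses$peak_velocity[j],
                                   presses$onset[j], fs)
      t_peaks[j] <- w$t_peak
      seg <- w$x
      if (presses$has_letgo[j]) {
        n_in <- round(2 * presses$amplitude[j] / presses$peak_velocity[j] * fs)
        seg <- c(seg[1:(n_in + 1)],
                 letgo_release(presses$amplitude[j], fs))
      }
      idx <- w$i0 + seq_along(seg)   # 1-based
      keep <- idx >= 1 & idx <= n
      x[idx[keep]] <- x[idx[keep]] + seg[keep]
    }
  }
  presses$t_peak_velocity <- t_peaks

  x <- x + with_seed(sub_seed(sim$seed, 2), {
    adj <- numeric(n)
    n_adj <- rpois(1, sim$microadjust_rate * sim$session_duration)
    if (n_adj > 0) {
      at <- sort(runif(n_adj, 1, sim$session_duration - 1))
      aa <- runif(n_adj, 0.2, 1.3)
      dd <- runif(n_adj, 0.10, 0.25)
      for (j in seq_len(n_adj)) {
        w <- microadjust_waveform(aa[j], dd[j], fs)
        idx <- round(at[j] * fs) + seq_along(w)
        keep <- idx >= 1 & idx <= n
        adj[idx[keep]] <- adj[idx[keep]] + w[keep]
      }
    }
    adj
  })

  if (sim$lever_noise_sd > 0)
    x <- x + with_seed(sub_seed(sim$seed, 3),
                       rnorm(n, 0, sim$lever_noise_sd))

  lever <- lever_trace(x, fs, provenance = list(
    sign = "inward_positive", source = "synthetic", seed = sim$seed))
  log <- run_task(lever, task)

  # optogenetic manipulation flags and pulse schedule
  opto_trials <- integer(0); pulse_times <- numeric(0)
  if (sim$opto$fraction > 0 && nrow(log$trials) >= sim$opto$start_trial) {
    eligible <- log$trials$trial_index[log$trials$trial_index >= sim$opto$start_trial]
    n_pick <- floor(sim$opto$fraction * length(eligible))
    if (n_pick > 0) {
      opto_trials <- with_seed(sub_seed(sim$seed, 4),
                               sort(sample(eligible, n_pick)))
      log$trials$manipulation_flag <- log$trials$trial_index %in% opto_trials
      starts <- log$trials$start_time[match(opto_trials, log$trials$trial_index)]
      np <- round(sim$opto$pulse_rate * sim$opto$train_duration)
      pulse_times <- as.numeric(vapply(starts, function(s)
        s + (0:(np - 1)) / sim$opto$pulse_rate, numeric(np)))
      opto_ev <- rbind(
        data.frame(time = starts, kind = "opto_on",
                   trial_index = opto_trials),
        data.frame(time = starts + sim$opto$train_duration, kind = "opto_off",
                   trial_index = opto_trials))
      log$events <- rbind(log$events, opto_ev)
      log$events <- log$events[order(log$events$time), , drop = FALSE]
      rownames(log$events) <- NULL
    }
  }

  rew <- log$trials$reward_time[log$trials$outcome == "rewarded"]
  truth <- list(presses = presses, reward_times = rew,
                opto_trials = opto_trials, pulse_times = pulse_times)
  structure(list(lever = lever, log = log, truth = truth,
                 sim = sim, task = task),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %.0f s, %d injected presses, %d trials (%d rewarded)\n",
              x$sim$session_duration, nrow(x$truth$presses),
              nrow(x$log$trials), sum(x$log$trials$outcome == "rewarded")))
  invisible(x)
}

#' Brute-force replay of ground-truth presses through the task rules
#'
#' Independent event-level checker: given only the injected press parameters,
#' it reconstructs each press waveform, locates its threshold-crossing
#' samples, and walks the trial rules (hold period, reward window, timeout,
#' ITI, threshold shift) press by press, without any shared state-machine
#' code. Used to verify that [run_task()]'s reward decisions on the emitted
#' trace match what the injected presses imply.
#'
#' Assumes presses are the only deflections (generate the session with
#' `microadjust_rate = 0` and negligible noise for exact comparisons).
#'
#' @param truth ground truth from [simulate_session()].
#' @param task the [task_config()] used.
#' @param fs lever sampling rate (Hz).
#' @param n_samples number of samples in the session trace.
#' @return Data frame, one row per injected press: `onset`, `trial_index`
#'   (NA if no trial was in progress), `rewarded`, and `trial_completed`
#'   (whether the containing trial ends within the record; the online
#'   controller discards trials cut off by the end of the trace).
#' @export
replay_ground_truth <- function(truth, task, fs, n_samples) {
  pr <- truth$presses
  hold_n <- round(task$no_move_hold * fs)
  window_n <- round(task$reward_window * fs)
  delay_n <- round(task$reward_delay * fs)
  timeout_n <- round(task$trial_timeout * fs)
  iti_n <- round(task$iti * fs)

  out <- data.frame(onset = pr$onset, trial_index = NA_integer_,
                    rewarded = logical(nrow(pr)))
  first_still <- 0L      # sample where the current stillness run began
  iti_end <- 0L
  trial <- 0L
  in_trial <- FALSE
  start_i <- NA_integer_; timeout_i <- NA_integer_
  trial_end <- integer(0)    # end sample per trial index (NA = unresolved)

  for (j in seq_len(nrow(pr))) {
    # press geometry in samples
    w <- simulate_press_waveform(pr$amplitude[j], pr$peak_velocity[j],
                                 pr$onset[j], fs)
    seg <- w$x
    if (pr$has_letgo[j]) {
      n_in <- round(2 * pr$amplitude[j] / pr$peak_velocity[j] * fs)
      seg <- c(seg[1:(n_in + 1)], letgo_release(pr$amplitude[j], fs))
    }
    idx <- w$i0 + seq_along(seg) - 1L    # 0-based sample indices
    det_c <- idx[which(seg >= task$detection_threshold)[1]]
    deflected <- which(abs(seg) >= task$detection_threshold)
    last_defl <- idx[deflected[length(deflected)]]

    repeat {
      if (!in_trial) {
        s <- max(first_still + hold_n, iti_end)
        if (s < det_c && s <= n_samples - 1) {
          trial <- trial + 1L
          in_trial <- TRUE; start_i <- s; timeout_i <- s + timeout_n
          trial_end[trial] <- NA_integer_
        } else break   # press begins before a trial could start
      }
      if (det_c >= timeout_i) {   # trial times out before this press
        in_trial <- FALSE
        trial_end[trial] <- timeout_i
        iti_end <- timeout_i + iti_n
        next
      }
      break
    }

    if (in_trial && det_c > start_i) {
      out$trial_index[j] <- trial
      rthr <- reward_threshold_for_trial(task, trial)
      rc_rel <- which(seg >= rthr)[1]
      if (!is.na(rc_rel)) {
        rew_c <- idx[rc_rel]
        if ((rew_c - det_c) < window_n && rew_c < timeout_i &&
            (rew_c + delay_n) <= n_samples - 1) {
          out$rewarded[j] <- TRUE
          in_trial <- FALSE
          trial_end[trial] <- rew_c + delay_n
          iti_end <- rew_c + delay_n + iti_n
        }
      }
      # unrewarded press: trial keeps running until timeout or a later press
    }
    first_still <- last_defl + 1L
  }
  if (in_trial)
    trial_end[trial] <- if (timeout_i <= n_samples - 1) timeout_i else NA_integer_
  out$trial_completed <- !is.na(out$trial_index) &
    !is.na(trial_end[pmax(out$trial_index, 1L)]) &
    !is.na(out$trial_index)
  out
}
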