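instantaneous_velocity <- function(x, fs) {
  n <- length(x)
  if (n < 3) return(rep(0, n))
  c((x[2] - x[1]) * fs,
    (x[3:n] - x[1:(n - 2)]) * fs / 2,
    (x[n] - x[n - 1]) * fs)
}

#' Movement segments of a lever trace
#'
#' Maximal contiguous intervals during which the instantaneous inward
#' velocity (central difference on the filtered trace) exceeds `v_cut`.
#'
#' @param trace a filtered [lever_trace()].
#' @param v_cut velocity cutoff (mm/s), default 5.
#' @return Data frame with half-open intervals `[t0, t1)` and the
#'   corresponding 1-based sample index range `i0:i1`.
#' @export
find_movement_segments <- function(trace, v_cut = 5) {
  stopifnot(inherits(trace, "lever_trace"))
  v <- instantaneous_velocity(trace$position, trace$fs)
  above <- v > v_cut
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(t0 = trace$t0 + (starts[keep] - 1) / trace$fs,
             t1 = trace$t0 + ends[keep] / trace$fs,
             i0 = starts[keep], i1 = ends[keep])
}

# press windows inside [ia, ib] (1-based sample indices): a window opens at a
# rising crossing of the detection threshold and closes when the position has
# stayed below it for at least dwell_n samples (so brief dips during riding
# deflections or let-go ringing do not split a press)
press_windows <- function(x, ia, ib, det, dwell_n) {
  seg <- x[ia:ib]
  above <- seg >= det
  if (!any(above)) return(NULL)
  r <- rle(above)
  # merge short below-threshold runs into the surrounding press
  vals <- r$values; lens <- r$lengths
  for (k in seq_along(vals)) {
    if (!vals[k] && k > 1 && k < length(vals) && lens[k] < dwell_n)
      vals[k] <- TRUE
  }
  r2 <- rle(rep(vals, lens))
  ends <- cumsum(r2$lengths); starts <- ends - r2$lengths + 1
  keep <- r2$values
  w <- cbind(start = starts[keep], end = ends[keep])
  # drop a leading window that was already open at ia (no rising edge)
  if (nrow(w) && w[1, "start"] == 1 && ia > 1 && x[ia - 1] >= det)
    w <- w[-1, , drop = FALSE]
  if (!nrow(w)) return(NULL)
  w[, "start"] <- w[, "start"] + ia - 1
  w[, "end"] <- w[, "end"] + ia - 1
  w
}

#' Detect presses and extract their kinematics
#'
#' One press per lever excursion exceeding the press threshold within a
#' trial. A press window opens at the detection-threshold crossing and closes
#' once the lever has stayed below the detection threshold for `dwell`
#' seconds, so sequential deflections riding on one another belong to one
#' press. Amplitude is the furthest inward distance reached in the window;
#' peak velocity is the largest instantaneous velocity over the window's
#' movement segments (velocity > `v_cut` inward). With
#' `exclude_letgo = TRUE`, windows are truncated at the first time the lever
#' travels back through rest and overshoots it outward by more than
#' `overshoot` mm (let-go oscillation artifacts), and kinematics are
#' recomputed on the truncated window.
#'
#' @param trace a preprocessed [lever_trace()] (see [preprocess_lever()]).
#' @param log the session `trial_log` (from [run_task()] or acquisition).
#' @param cfg the [task_config()] in force.
#' @param v_cut movement-segment velocity cutoff (mm/s).
#' @param dwell below-detection dwell closing a press window (s).
#' @param exclude_letgo apply the let-go exclusion rule.
#' @param overshoot outward overshoot (mm) triggering exclusion (strict).
#' @return A `press_table` data frame: `trial_index`, `onset_s`, `t_end_s`,
#'   `amplitude_mm`, `peak_velocity_mm_s`, `t_peak_velocity_s`, `rewarded`,
#'   `manipulation_flag`, `excluded_after_s`.
#' @export
detect_presses <- function(trace, log, cfg, v_cut = 5, dwell = 0.05,
                           exclude_letgo = TRUE, overshoot = 2.5) {
  stopifnot(inherits(trace, "lever_trace"), inherits(log, "trial_log"),
            inherits(cfg, "task_config"))
  fs <- trace$fs
  n <- length(trace$position)
  t_end_trace <- trace$t0 + n / fs
  if (nrow(log$trials) &&
      (min(log$trials$start_time) < trace$t0 - 1 / fs ||
       max(log$trials$end_time) > t_end_trace + 1 / fs))
    stop_pv("pressvigor_error_alignment",
            "trial log times fall outside the lever trace span")
  x <- trace$position
  v <- instantaneous_velocity(x, fs)
  dwell_n <- max(1, round(dwell * fs))

  rc <- log$events[log$events$kind == "reward_cross", , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(log$trials))) {
    tr <- log$trials[k, ]
    ia <- max(1L, floor((tr$start_time - trace$t0) * fs) + 1L)
    ib <- min(n, ceiling((tr$end_time - trace$t0) * fs))
    if (ib <= ia) next
    w <- press_windows(x, ia, ib, cfg$detection_threshold, dwell_n)
    if (is.null(w)) next
    for (j in seq_len(nrow(w))) {
      i0 <- w[j, "start"]; i1 <- w[j, "end"]
      pr <- press_kinematics(x, v, fs, trace$t0, i0, i1, v_cut,
                             if (exclude_letgo) overshoot else NA_real_)
      if (pr$amplitude < cfg$press_threshold) next
      t_on <- trace$t0 + (i0 - 1) / fs
      rewarded <- identical(tr$outcome, "rewarded") &&
        any(rc$trial_index == tr$trial_index &
            rc$time >= t_on - 0.5 / fs & rc$time < pr$t_end)
      rows[[length(rows) + 1L]] <- data.frame(
        trial_index = tr$trial_index, onset_s = t_on, t_end_s = pr$t_end,
        amplitude_mm = pr$amplitude, peak_velocity_mm_s = pr$peak_velocity,
        t_peak_velocity_s = pr$t_peak_velocity, rewarded = rewarded,
        manipulation_flag = tr$manipulation_flag,
        excluded_after_s = pr$excluded_after)
    }
  }
  out <- if (length(rows)) {
    o <- do.call(rbind, rows); rownames(o) <- NULL; o
  } else data.frame(
    trial_index = integer(), onset_s = numeric(), t_end_s = numeric(),
    amplitude_mm = numeric(), peak_velocity_mm_s = numeric(),
    t_peak_velocity_s = numeric(), rewarded = logical(),
    manipulation_flag = logical(), excluded_after_s = numeric())
  class(out) <- c("press_table", "data.frame")
  out
}

# kinematics of one press window, optionally truncated at the let-go
# overshoot point (first sample strictly below -overshoot)
press_kinematics <- function(x, v, fs, t0, i0, i1, v_cut, overshoot) {
  excluded_after <- NA_real_
  if (!is.na(overshoot)) {
    osc <- which(x[i0:i1] < -overshoot)
    if (length(osc)) {
      i_ex <- i0 + osc[1] - 1L
      excluded_after <- t0 + (i_ex - 1) / fs
      i1 <- i_ex - 1L
    }
  }
  win_x <- x[i0:i1]; win_v <- v[i0:i1]
  amp <- max(win_x)
  seg_v <- win_v[win_v > v_cut]
  if (length(seg_v)) {
    pk <- max(seg_v)
    ipk <- i0 + which(win_v == pk)[1] - 1L
  } else {
    pk <- max(win_v)
    ipk <- i0 + which.max(win_v) - 1L
  }
  list(amplitude = amp, peak_velocity = pk,
       t_peak_velocity = t0 + (ipk - 1) / fs,
       t_end = t0 + i1 / fs, excluded_after = excluded_after)
}

#' Apply the let-go exclusion rule to one detected press
#'
#' Truncates the press's analysis window at the first time the lever
#' overshoots the rest position outward by strictly more than `overshoot` mm,
#' and recomputes amplitude and peak velocity on the truncated window. A
#' press without such an overshoot is returned unchanged.
#'
#' @param press one row of a `press_table`.
#' @param trace the [lever_trace()] the press was detected on.
#' @param overshoot outward overshoot threshold (mm), strict.
#' @param v_cut movement-segment velocity cutoff (mm/s).
#' @return The (possibly truncated) press row with `excluded_after_s` set.
#' @export
exclude_letgo <- function(press, trace, overshoot = 2.5, v_cut = 5) {
  stopifnot(nrow(press) == 1, inherits(trace, "lever_trace"))
  fs <- trace$fs
  x <- trace$position
  v <- instantaneous_velocity(x, fs)
  i0 <- round((press$onset_s - trace$t0) * fs) + 1L
  i1 <- round((press$t_end_s - trace$t0) * fs)
  pr <- press_kinematics(x, v, fs, trace$t0, i0, i1, v_cut, overshoot)
  press$amplitude_mm <- pr$amplitude
  press$peak_velocity_mm_s <- pr$peak_velocity
  press$t_peak_velocity_s <- pr$t_peak_velocity
  press$t_end_s <- pr$t_end
  press$excluded_after_s <- pr$excluded_after
  press
}
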