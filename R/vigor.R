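#' Bootstrap estimate of a population median
#'
#' Resamples `values` with replacement `n_boot` times; the point estimate is
#' the mean of the resampled medians (stabler than the raw median for small
#' or imbalanced samples), with a percentile 95% confidence interval. The raw
#' sample median is reported alongside for transparency.
#'
#' @param values numeric vector, non-empty.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed optional integer seed for reproducible resampling.
#' @return List: `estimate`, `ci` (2.5/97.5 percentiles), `median` (raw),
#'   `n`, `n_boot`.
#' @export
bootstrap_median <- function(values, n_boot = 1000, seed = NULL) {
  values <- values[is.finite(values)]
  if (!length(values))
    stop_pv("pressvigor_error_input", "no finite values to bootstrap")
  meds <- boot_medians(values, n_boot, seed)
  list(estimate = mean(meds),
       ci = unname(quantile(meds, c(0.025, 0.975))),
       median = median(values), n = length(values), n_boot = n_boot)
}

boot_medians <- function(values, n_boot, seed = NULL) {
  draw <- function() {
    n <- length(values)
    m <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    apply(m, 2, function(i) median(values[i]))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Percent change of a vigor metric relative to control
#'
#' `(manipulation - control) * 100 / control`.
#'
#' @param manip_median metric under manipulation.
#' @param control_median metric under control trials.
#' @return Percent change.
#' @export
percent_change <- function(manip_median, control_median) {
  if (any(control_median == 0))
    stop_pv("pressvigor_error_input", "control median is zero")
  (manip_median - control_median) * 100 / control_median
}

#' Session-level vigor summary
#'
#' Bootstrap-median press amplitude and peak velocity for a session, overall
#' and split by the manipulation flag (control vs manipulation trials).
#'
#' @param presses a `press_table` from [detect_presses()].
#' @param n_boot bootstrap resamples.
#' @param seed optional seed.
#' @return An object of class `session_vigor`.
#' @export
session_vigor <- function(presses, n_boot = 1000, seed = NULL) {
  if (!nrow(presses))
    stop_pv("pressvigor_error_input", "no presses in session")
  summ <- function(df, s_off) {
    if (!nrow(df)) return(NULL)
    list(n_presses = nrow(df),
         amplitude = bootstrap_median(df$amplitude_mm, n_boot,
                                      if (is.null(seed)) NULL else seed + s_off),
         peak_velocity = bootstrap_median(df$peak_velocity_mm_s, n_boot,
                                          if (is.null(seed)) NULL else seed + s_off + 1))
  }
  out <- list(overall = summ(presses, 0),
              control = summ(presses[!presses$manipulation_flag, ], 10),
              manipulation = summ(presses[presses$manipulation_flag, ], 20))
  structure(out, class = "session_vigor")
}

#' @export
print.session_vigor <- function(x, ...) {
  f <- function(lbl, s) {
    if (is.null(s)) return(invisible())
    cat(sprintf("  %-13s n=%4d  amplitude %.2f mm [%.2f, %.2f]  peak velocity %.1f mm/s [%.1f, %.1f]\n",
                lbl, s$n_presses, s$amplitude$estimate, s$amplitude$ci[1],
                s$amplitude$ci[2], s$peak_velocity$estimate,
                s$peak_velocity$ci[1], s$peak_velocity$ci[2]))
  }
  cat("<session_vigor>\n")
  f("overall", x$overall); f("control", x$control); f("manipulation", x$manipulation)
  invisible(x)
}

boot_percent_change <- function(pre, post, n_boot, seed) {
  draws <- function() {
    vapply(seq_len(n_boot), function(b) {
      pc <- median(sample(post, replace = TRUE))
      pr <- median(sample(pre, replace = TRUE))
      (pc - pr) * 100 / pr
    }, numeric(1))
  }
  d <- if (is.null(seed)) draws() else with_seed(seed, draws())
  list(estimate = mean(d), ci = unname(quantile(d, c(0.025, 0.975))),
       point = percent_change(median(post), median(pre)))
}

#' Vigor change around the uncued reward-threshold shift
#'
#' Compares press amplitude and peak velocity between the 30 consecutive
#' trials before the threshold shift and the 200 s that follow it, as
#' bootstrap percent changes.
#'
#' @param presses a `press_table`.
#' @param log the session `trial_log`.
#' @param shift_trial trial index at which the threshold was raised.
#' @param n_pre_trials number of pre-shift trials (default 30).
#' @param window_s post-shift window (s, default 200).
#' @param n_boot,seed bootstrap settings.
#' @return List with per-metric percent-change estimates and CIs, plus the
#'   press counts in each window.
#' @export
threshold_shift_contrast <- function(presses, log, shift_trial,
                                     n_pre_trials = 30, window_s = 200,
                                     n_boot = 1000, seed = NULL) {
  tr <- log$trials
  if (!shift_trial %in% tr$trial_index)
    stop_pv("pressvigor_error_input",
            sprintf("shift_trial %d beyond session (last trial %d)",
                    shift_trial, max(c(0, tr$trial_index))))
  n_pre_avail <- sum(tr$trial_index < shift_trial)
  if (n_pre_avail < n_pre_trials)
    stop_pv("pressvigor_error_input",
            sprintf("need %d pre-shift trials, session has %d",
                    n_pre_trials, n_pre_avail))
  t_shift <- tr$start_time[tr$trial_index == shift_trial]
  pre_set <- (shift_trial - n_pre_trials):(shift_trial - 1)
  pre <- presses[presses$trial_index %in% pre_set, ]
  post <- presses[presses$onset_s >= t_shift &
                  presses$onset_s < t_shift + window_s, ]
  if (!nrow(pre) || !nrow(post))
    stop_pv("pressvigor_error_input",
            sprintf("insufficient presses (pre %d, post %d)",
                    nrow(pre), nrow(post)))
  list(amplitude = boot_percent_change(pre$amplitude_mm, post$amplitude_mm,
                                       n_boot, seed),
       peak_velocity = boot_percent_change(pre$peak_velocity_mm_s,
                                           post$peak_velocity_mm_s, n_boot,
                                           if (is.null(seed)) NULL else seed + 1),
       n_pre = nrow(pre), n_post = nrow(post), t_shift = t_shift)
}

#' Vigor on manipulated trials versus the following trial
#'
#' Contrasts presses on manipulation-flagged trials (trial n) with presses on
#' the immediately following trials (n + 1, themselves unflagged), to probe
#' delayed manipulation effects.
#'
#' @param presses a `press_table`.
#' @param log the session `trial_log`.
#' @return List with per-metric medians and percent changes (successor vs
#'   flagged) and press counts; `n_successor` may be 0, in which case the
#'   changes are `NA` (reported, not an error).
#' @export
next_trial_contrast <- function(presses, log) {
  tr <- log$trials
  flagged <- tr$trial_index[tr$manipulation_flag]
  if (!length(flagged))
    stop_pv("pressvigor_error_input", "no manipulation-flagged trials in log")
  succ <- (flagged + 1)
  succ <- succ[succ %in% tr$trial_index[!tr$manipulation_flag]]
  p_m <- presses[presses$trial_index %in% flagged, ]
  p_s <- presses[presses$trial_index %in% succ, ]
  med <- function(df) c(amplitude = median(df$amplitude_mm),
                        peak_velocity = median(df$peak_velocity_mm_s))
  m_m <- med(p_m)
  m_s <- if (nrow(p_s)) med(p_s) else c(amplitude = NA_real_,
                                        peak_velocity = NA_real_)
  list(manipulated = m_m, successor = m_s,
       change = if (nrow(p_s)) percent_change(m_s, m_m)
                else c(amplitude = NA_real_, peak_velocity = NA_real_),
       n_manipulated = nrow(p_m), n_successor = nrow(p_s))
}
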