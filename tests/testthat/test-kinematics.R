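test_that("lever preprocessing matches the analytic zero-phase Butterworth response", {
  fs_in <- 2000
  n <- fs_in * 20
  # constant trace passes through unchanged
  cst <- preprocess_lever(lever_trace(rep(2.5, n), fs_in))
  expect_equal(cst$position, rep(2.5, n / 2), tolerance = 1e-6)
  expect_equal(cst$fs, 1000)
  # probe sinusoids in pass- and transition band
  for (f in c(5, 10, 20)) {
    x <- sin(2 * pi * f * (0:(n - 1)) / fs_in)
    y <- preprocess_lever(lever_trace(x, fs_in))$position
    g <- max(y[2000:8000])     # away from filter edges
    expect_lt(abs(g - butter_zerophase_gain(f, 30, 6)), 0.01)
  }
  # deep stopband: 100 Hz, 1-mm sinusoid comes out far below 0.01 mm
  x <- sin(2 * pi * 100 * (0:(n - 1)) / fs_in)
  y <- preprocess_lever(lever_trace(x, fs_in))$position
  expect_lt(max(abs(y[2000:8000])), 0.01)
  expect_error(preprocess_lever(lever_trace(rep(0, 100), 1000)),
               class = "pressvigor_error_format")
})

test_that("movement segments are velocity-thresholded maximal runs", {
  fs <- 1000
  expect_equal(nrow(find_movement_segments(lever_trace(rep(1, 2000), fs))), 0)
  # linear ramp at 10 mm/s for 0.5 s -> one segment of ~0.5 s
  x <- c(rep(0, 500), seq(0, 5, by = 10 / fs), rep(5, 500))
  seg <- find_movement_segments(lever_trace(x, fs))
  expect_equal(nrow(seg), 1)
  expect_lt(abs((seg$t1 - seg$t0) - 0.5), 3 / fs)
  # velocity pulse peaking below the cutoff -> nothing
  w <- simulate_press_waveform(0.2, 4, onset = 0.5, fs = fs)
  x2 <- rep(0, 2000); x2[w$i0 + seq_along(w$x)] <- w$x
  expect_equal(nrow(find_movement_segments(lever_trace(x2, fs))), 0)
  # raising v_cut never increases segment count or total duration
  s <- clean_session(seed = 8, duration = 90)
  cuts <- c(5, 10, 20, 40)
  segs <- lapply(cuts, function(vc) find_movement_segments(s$lever, vc))
  n_seg <- vapply(segs, nrow, integer(1))
  dur <- vapply(segs, function(g) sum(g$t1 - g$t0), numeric(1))
  expect_true(all(diff(dur) <= 1e-9))
  expect_true(all(n_seg[dur == 0] == 0))
})

test_that("press detection respects the press threshold and trial structure", {
  fs <- 1000
  # 1.5-mm excursion: crosses detection but is below the press threshold
  tr <- scripted_press_trace(amp = 1.5)
  log <- run_task(tr, task_config())
  pr <- detect_presses(tr, log, task_config())
  expect_equal(nrow(pr), 0)
  # an empty trial produces no press
  tr2 <- lever_trace(rep(0, 40000), fs)
  log2 <- run_task(tr2, task_config())
  expect_equal(nrow(detect_presses(tr2, log2, task_config())), 0)
  # misaligned log raises an alignment error
  s <- clean_session(seed = 30, duration = 60)
  log3 <- s$log
  log3$trials$end_time <- log3$trials$end_time + 100
  expect_error(detect_presses(s$lever, log3, task_config()),
               class = "pressvigor_error_alignment")
})

test_that("detected kinematics recover injected presses within tolerance", {
  s <- clean_session(seed = 14, duration = 300, fs = 2000)
  lev <- preprocess_lever(s$lever)
  pr <- detect_presses(lev, s$log, task_config())
  gt <- s$truth$presses
  # every detected press matches one ground-truth press
  m <- vapply(pr$onset_s, function(o) which.min(abs(gt$onset - o)), integer(1))
  expect_true(all(abs(gt$onset[m] - pr$onset_s) < 0.3))
  rel_amp <- abs(pr$amplitude_mm - gt$amplitude[m]) / gt$amplitude[m]
  expect_lt(median(rel_amp), 0.02)
  # rewarded flags agree with the trial log
  expect_equal(sum(pr$rewarded), sum(s$log$trials$outcome == "rewarded"))
  # reward consistency: every rewarded press reached the threshold in force
  rew <- pr[pr$rewarded, ]
  thr <- vapply(rew$trial_index,
                function(ti) reward_threshold_for_trial(task_config(), ti),
                numeric(1))
  expect_true(all(rew$amplitude_mm >= thr - 0.02))
})

test_that("let-go exclusion restores kinematics of artifacted presses", {
  # paired sessions differing only in the presence of let-go releases
  s_clean <- simulate_session(
    sim_config(seed = 33, session_duration = 300, fs = 2000, letgo_prob = 0,
               microadjust_rate = 0, lever_noise_sd = 0), task_config())
  s_art <- simulate_session(
    sim_config(seed = 33, session_duration = 300, fs = 2000, letgo_prob = 1,
               microadjust_rate = 0, lever_noise_sd = 0), task_config())
  expect_equal(s_clean$truth$presses$onset, s_art$truth$presses$onset)
  pc <- detect_presses(preprocess_lever(s_clean$lever), s_clean$log, task_config())
  pa <- detect_presses(preprocess_lever(s_art$lever), s_art$log, task_config())
  m <- match(round(pa$onset_s, 2), round(pc$onset_s, 2))
  ok <- !is.na(m)
  expect_gt(sum(ok), 0.9 * nrow(pa))
  expect_true(any(!is.na(pa$excluded_after_s)))
  dv <- abs(pa$peak_velocity_mm_s[ok] / pc$peak_velocity_mm_s[m[ok]] - 1)
  expect_lt(median(dv), 0.01)
  # without exclusion, the ringing grossly inflates peak velocity
  pa_raw <- detect_presses(preprocess_lever(s_art$lever), s_art$log,
                           task_config(), exclude_letgo = FALSE)
  expect_gt(median(pa_raw$peak_velocity_mm_s), 2 * median(pa$peak_velocity_mm_s))
})

test_that("exclusion is strict: an overshoot of exactly 2.5 mm is kept", {
  fs <- 1000
  w <- simulate_press_waveform(5, 80, onset = 0.5, fs = fs)
  x <- rep(0, 4000)
  x[w$i0 + seq_along(w$x)] <- w$x
  i_end <- w$i0 + length(w$x)
  x[(i_end + 1):(i_end + 40)] <- -2.5          # exactly at the boundary
  press <- data.frame(trial_index = 1L, onset_s = 0.5,
                      t_end_s = (i_end + 60) / fs, amplitude_mm = 5,
                      peak_velocity_mm_s = 80, t_peak_velocity_s = 0.56,
                      rewarded = TRUE, manipulation_flag = FALSE,
                      excluded_after_s = NA_real_)
  out <- exclude_letgo(press, lever_trace(x, fs))
  expect_true(is.na(out$excluded_after_s))
  x[(i_end + 1):(i_end + 40)] <- -2.6          # strictly beyond: excluded
  out2 <- exclude_letgo(press, lever_trace(x, fs))
  expect_false(is.na(out2$excluded_after_s))
})

test_that("bootstrap medians behave on degenerate, known and seeded inputs", {
  b <- bootstrap_median(rep(7, 20), n_boot = 200, seed = 1)
  expect_equal(b$estimate, 7)
  expect_equal(unname(diff(b$ci)), 0)
  # Exp(1): median ln 2, estimate within 3 standard errors
  set.seed(40)
  v <- rexp(1000)
  b2 <- bootstrap_median(v, n_boot = 1000, seed = 2)
  se <- sd(replicate(200, median(sample(v, replace = TRUE))))
  expect_lt(abs(b2$estimate - log(2)), 3 * se + 0.05)
  expect_identical(bootstrap_median(v, 500, seed = 7),
                   bootstrap_median(v, 500, seed = 7))
  expect_error(bootstrap_median(numeric(0)), class = "pressvigor_error_input")
})

test_that("percent change is the plain ratio formula", {
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(1.1 * 3, 3), 10)
  expect_equal(percent_change(90, 120), -25)
  expect_error(percent_change(1, 0), class = "pressvigor_error_input")
})

test_that("threshold-shift contrast recovers injected vigor changes", {
  # build a synthetic press table directly: 60 trials pre, presses post
  set.seed(11)
  mk <- function(n, t0, amp_scale = 1, vel_scale = 1, trial0 = 1) {
    data.frame(trial_index = trial0 + seq_len(n) - 1,
               onset_s = t0 + seq_len(n) * 4,
               t_end_s = t0 + seq_len(n) * 4 + 0.3,
               amplitude_mm = amp_scale * rlnorm(n, log(4.8), 0.2),
               peak_velocity_mm_s = vel_scale * rlnorm(n, log(85), 0.2),
               t_peak_velocity_s = t0 + seq_len(n) * 4 + 0.05,
               rewarded = TRUE, manipulation_flag = FALSE,
               excluded_after_s = NA_real_)
  }
  pre <- mk(60, 0)
  post <- mk(40, 245, amp_scale = 1.2, trial0 = 61)
  presses <- rbind(pre, post)
  log <- list(trials = data.frame(
    trial_index = 1:100, start_time = c(seq_len(60) * 4 - 1, 244 + seq_len(40) * 4),
    end_time = c(seq_len(60) * 4 + 1, 246 + seq_len(40) * 4),
    outcome = "rewarded", reward_time = NA_real_, manipulation_flag = FALSE))
  class(log) <- "trial_log"
  out <- threshold_shift_contrast(presses, log, shift_trial = 61,
                                  n_boot = 500, seed = 3)
  expect_lt(abs(out$amplitude$estimate - 20), diff(out$amplitude$ci))
  expect_lt(abs(out$peak_velocity$estimate),
            diff(out$peak_velocity$ci))    # null metric stays near 0
  expect_error(threshold_shift_contrast(presses, log, shift_trial = 500),
               class = "pressvigor_error_input")
  expect_error(threshold_shift_contrast(presses, log, shift_trial = 10),
               class = "pressvigor_error_input")  # too few pre-shift trials
})

test_that("next-trial contrast compares flagged trials with their successors", {
  set.seed(12)
  n <- 90
  flagged <- seq(5, 85, by = 10)
  presses <- data.frame(trial_index = 1:n, onset_s = (1:n) * 4,
                        t_end_s = (1:n) * 4 + 0.3,
                        amplitude_mm = rlnorm(n, log(4.8), 0.15),
                        peak_velocity_mm_s = rlnorm(n, log(85), 0.15),
                        t_peak_velocity_s = (1:n) * 4 + 0.05,
                        rewarded = TRUE,
                        manipulation_flag = (1:n) %in% flagged,
                        excluded_after_s = NA_real_)
  # successors 10% faster
  presses$peak_velocity_mm_s[presses$trial_index %in% (flagged + 1)] <-
    1.10 * presses$peak_velocity_mm_s[presses$trial_index %in% flagged]
  log <- list(trials = data.frame(trial_index = 1:n, start_time = (1:n) * 4 - 1,
                                  end_time = (1:n) * 4 + 1, outcome = "rewarded",
                                  reward_time = NA_real_,
                                  manipulation_flag = (1:n) %in% flagged))
  class(log) <- "trial_log"
  out <- next_trial_contrast(presses, log)
  expect_equal(out$n_manipulated, length(flagged))
  expect_lt(abs(out$change[["peak_velocity"]] - 10), 4)
  # no flagged trials is an error
  log0 <- log; log0$trials$manipulation_flag <- FALSE
  expect_error(next_trial_contrast(presses, log0),
               class = "pressvigor_error_input")
  # successors without presses are reported, not an error
  p2 <- presses[!presses$trial_index %in% (flagged + 1), ]
  out2 <- next_trial_contrast(p2, log)
  expect_equal(out2$n_successor, 0)
  expect_true(all(is.na(out2$change)))
})
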