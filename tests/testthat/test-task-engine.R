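test_that("a flat trace yields hold-then-timeout trials with correct timing", {
  tr <- lever_trace(rep(0, 65000), 1000)
  log <- run_task(tr, task_config())
  expect_equal(log$trials$start_time[1], 0.3)
  expect_equal(log$trials$outcome[1], "timeout")
  expect_equal(log$trials$end_time[1], 30.3)
  # next trial follows the 1-s ITI (lever still throughout)
  expect_equal(log$trials$start_time[2], 31.3)
})

test_that("a fast suprathreshold press is rewarded with 0.5-s delayed delivery", {
  tr <- scripted_press_trace(hold_s = 0.4, ramp_s = 0.08, amp = 5)
  log <- run_task(tr, task_config())
  expect_equal(log$trials$outcome[1], "rewarded")
  ev <- log$events
  rc <- ev$time[ev$kind == "reward_cross"]
  rd <- ev$time[ev$kind == "reward_delivery"]
  expect_equal(rd, rc + 0.5)
  expect_equal(log$trials$reward_time[1], rd)
  # the reward crossing is within the 0.5-s window of the detection crossing
  dc <- ev$time[ev$kind == "detection_cross"][1]
  expect_lt(rc - dc, 0.5)
})

test_that("a deflection during the hold postpones trial start", {
  fs <- 1000
  x <- rep(0, 35000)
  x[201:260] <- 1.0   # 1-mm blip at t = 0.2 s lasting 60 ms
  log <- run_task(lever_trace(x, fs), task_config())
  # blip ends at t = 0.260 (last sample >= detection); restart hold after it
  expect_gt(log$trials$start_time[1], 0.26 + 0.3 - 0.005)
  expect_lt(log$trials$start_time[1], 0.26 + 0.3 + 0.015)
})

test_that("a press crossing the reward threshold too late is not rewarded", {
  # slow ramp: detection crossing to reward crossing takes > 0.5 s
  fs <- 1000
  x <- rep(0, 40000)
  n_ramp <- 900  # 0.9 s to reach 5 mm
  x[501:(500 + n_ramp)] <- seq(0, 5, length.out = n_ramp)
  x[(500 + n_ramp + 1):(500 + 2 * n_ramp)] <- seq(5, 0, length.out = n_ramp)
  log <- run_task(lever_trace(x, fs), task_config())
  expect_equal(log$trials$outcome[1], "timeout")
  expect_false("reward_cross" %in% log$events$kind)
  expect_true("press_cross" %in% log$events$kind)
})

test_that("threshold shift raises the reward threshold from the given trial", {
  cfg <- task_config(reward_threshold = 4.0)
  cfg2 <- apply_threshold_shift(cfg, 80)
  expect_equal(reward_threshold_for_trial(cfg2, 79), 4.0)
  expect_equal(reward_threshold_for_trial(cfg2, 80), 4.4)
  expect_equal(reward_threshold_for_trial(cfg2, 120), 4.4)
  # original config unchanged
  expect_true(is.na(cfg$shift_trial))
  # zero shift fraction scores identically
  s <- clean_session(seed = 4, duration = 90)
  l0 <- run_task(s$lever, task_config())
  l1 <- run_task(s$lever, apply_threshold_shift(task_config(), 3,
                                                shift_fraction = 0))
  expect_equal(l0$trials, l1$trials)
  # rewarded count is non-increasing under a +10% shift
  l2 <- run_task(s$lever, apply_threshold_shift(task_config(), 3))
  expect_lte(sum(l2$trials$outcome == "rewarded"),
             sum(l0$trials$outcome == "rewarded"))
  expect_error(apply_threshold_shift(cfg, 0), class = "pressvigor_error_config")
  expect_error(apply_threshold_shift(cfg, 5, shift_fraction = -1.5),
               class = "pressvigor_error_config")
})

test_that("run_task is deterministic and matches the naive reference interpreter", {
  for (seed in 1:6) {
    s <- simulate_session(
      sim_config(seed = seed, session_duration = 60, press_rate = 0.4,
                 letgo_prob = 0.15),
      task_config(shift_trial = 5))
    a <- run_task(s$lever, s$task)
    b <- run_task(s$lever, s$task)
    expect_identical(a, b)
    ref <- run_task_reference(s$lever, s$task)
    expect_equal(a$trials, ref$trials)
    expect_equal(a$events, ref$events)
  }
})

test_that("reward deliveries never occur during the ITI and reward crossings respect the window", {
  s <- simulate_session(sim_config(seed = 9, session_duration = 240,
                                   press_rate = 0.35),
                        task_config())
  ev <- s$log$events
  tr <- s$log$trials
  rd <- ev[ev$kind == "reward_delivery", ]
  # every delivery lies inside its trial, not in the ITI after it
  for (i in seq_len(nrow(rd))) {
    row <- tr[tr$trial_index == rd$trial_index[i], ]
    expect_lte(rd$time[i], row$end_time)
    expect_gte(rd$time[i], row$start_time)
  }
  # reward crossings within the reward window of a detection crossing
  for (ti in unique(rd$trial_index)) {
    e <- ev[ev$trial_index == ti, ]
    rc <- e$time[e$kind == "reward_cross"]
    dc <- e$time[e$kind == "detection_cross"]
    expect_true(any(rc - dc >= 0 & rc - dc < 0.5))
  }
})

test_that("a trace shorter than the hold period yields an empty log", {
  log <- run_task(lever_trace(rep(0, 100), 1000), task_config())
  expect_equal(nrow(log$trials), 0)
  expect_equal(nrow(log$events), 0)
})
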