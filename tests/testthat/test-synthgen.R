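test_that("press waveform hits requested amplitude and peak velocity", {
  w <- simulate_press_waveform(5, 100, onset = 0.5, fs = 1000)
  v <- diff(w$x) * 1000
  expect_lt(abs(max(w$x) - 5), 0.05)
  expect_lt(abs(max(v) - 100) / 100, 0.02)
  expect_equal(w$x[length(w$x)], 0)          # returns to rest
  expect_equal(w$i0, 500)
  # tiny amplitude: excursion ~ epsilon, velocity ~ requested
  w2 <- simulate_press_waveform(0.05, 2, fs = 1000)
  expect_lt(abs(max(w2$x) - 0.05), 0.005)
  expect_lt(abs(max(diff(w2$x) * 1000) - 2) / 2, 0.05)
  # determinism
  expect_identical(simulate_press_waveform(3, 80, 1, 1000),
                   simulate_press_waveform(3, 80, 1, 1000))
  # invalid / infeasible parameters
  expect_error(simulate_press_waveform(0, 100), class = "pressvigor_error_param")
  expect_error(simulate_press_waveform(-1, 100), class = "pressvigor_error_param")
  expect_error(simulate_press_waveform(1, 5000, fs = 1000),
               class = "pressvigor_error_param")
  err <- tryCatch(simulate_press_waveform(1, 5000, fs = 1000),
                  error = function(e) conditionMessage(e))
  expect_match(err, "bound")   # error names the feasibility bound
})

test_that("simulate_session is seed-reproducible and zero-rate sessions are empty", {
  s0 <- simulate_session(sim_config(seed = 2, session_duration = 60,
                                    press_rate = 0),
                         task_config())
  expect_equal(nrow(s0$truth$presses), 0)
  expect_equal(sum(s0$log$trials$outcome == "rewarded"), 0)
  a <- simulate_session(sim_config(seed = 3, session_duration = 60), task_config())
  b <- simulate_session(sim_config(seed = 3, session_duration = 60), task_config())
  expect_identical(a$lever$position, b$lever$position)
  expect_identical(a$log, b$log)
  expect_identical(a$truth, b$truth)
})

test_that("replaying ground truth through the brute-force checker reproduces reward decisions", {
  for (seed in c(5, 21)) {
    s <- clean_session(seed = seed, duration = 420, press_rate = 0.35)
    rp <- replay_ground_truth(s$truth, s$task, s$lever$fs,
                              length(s$lever$position))
    expect_equal(sum(rp$rewarded), sum(s$log$trials$outcome == "rewarded"))
    # rewarded presses are exactly the injected suprathreshold presses that
    # satisfied the crossing rule inside a trial
    rewarded_trials <- s$log$trials$trial_index[s$log$trials$outcome == "rewarded"]
    expect_setequal(rp$trial_index[rp$rewarded], rewarded_trials)
  }
})

test_that("an overly high press rate warns and thins gaps", {
  expect_warning(
    simulate_session(sim_config(seed = 1, session_duration = 30,
                                press_rate = 2), task_config()),
    "thinned")
})

test_that("photometry components sum exactly to the emitted trace", {
  s <- clean_session(seed = 6, duration = 90)
  out <- simulate_photometry(photom_sim_params(), s, duration = 90, fs = 200,
                             seed = 6)
  recon <- with(out$components, offset + tonic_v + phasic_v + artifact + noise)
  expect_equal(recon, out$trace$v, tolerance = 1e-12)
})

test_that("noise-free transient-free lesion photometry is a pure non-increasing bleach curve", {
  p <- photom_sim_params(condition = "lesion", noise_sd = 0,
                         spontaneous_transient_rate = 0)
  out <- simulate_photometry(p, list(reward_times = numeric(0)),
                             duration = 120, fs = 100, seed = 1)
  expect_true(all(diff(out$trace$v) <= 0))
  expect_true(all(out$components$phasic_v == 0))
})

test_that("negative composed fluorescence raises a config error", {
  p <- photom_sim_params(dark_offset = 0.0005, autofluorescence = 0.0005,
                         f_unbound = 0.001, tonic_level = 0.001,
                         noise_sd = 0.5)
  expect_error(simulate_photometry(p, list(reward_times = numeric(0)),
                                   duration = 60, fs = 100, seed = 1),
               class = "pressvigor_error_config")
})

test_that("condition invariants hold: lesion kills both components, drugs scale tonic", {
  expect_error(photom_sim_params(tonic_gain = c(saline = 1, raclopride = 0.8,
                                                levodopa = 1.5, lesion = 0.2)),
               class = "pressvigor_error_config")
  p <- photom_sim_params()
  expect_gt(p$tonic_gain[["levodopa"]], p$tonic_gain[["saline"]])
  expect_lt(p$tonic_gain[["raclopride"]], p$tonic_gain[["saline"]])
  expect_lt(p$phasic_gain[["raclopride"]], p$phasic_gain[["saline"]])
})

test_that("amplitude distributions must straddle the press and reward thresholds", {
  expect_error(sim_config(amplitude_dist = c(meanlog = log(1.0), sdlog = 0.1)),
               class = "pressvigor_error_config")
  expect_error(sim_config(amplitude_dist = c(meanlog = log(20), sdlog = 0.1)),
               class = "pressvigor_error_config")
})
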