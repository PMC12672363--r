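test_that("photometry preprocessing matches the analytic 10-pole response", {
  fs_in <- 2000; n <- fs_in * 20
  cst <- preprocess_photometry(photometry_trace(rep(1.5, n), fs_in))
  expect_equal(cst$v, rep(1.5, n / 2), tolerance = 1e-3)
  x <- sin(2 * pi * 2 * (0:(n - 1)) / fs_in)
  y <- preprocess_photometry(photometry_trace(x, fs_in))$v
  expect_lt(abs(max(y[3000:17000]) - butter_zerophase_gain(2, 30, 10)), 0.01)
  x2 <- sin(2 * pi * 200 * (0:(n - 1)) / fs_in)
  y2 <- preprocess_photometry(photometry_trace(x2, fs_in))$v
  expect_lt(max(abs(y2[3000:17000])), 1e-3)
  expect_error(preprocess_photometry(photometry_trace(rep(1, 100), 500)),
               class = "pressvigor_error_format")
})

test_that("initial-epoch normalization is recorded, guarded and scale-invariant", {
  fs <- 100
  cst <- normalize_to_initial(photometry_trace(rep(2, fs * 60), fs))
  expect_equal(cst$v, rep(1, fs * 60))
  expect_equal(cst$F0_estimate, 2)
  expect_equal(cst$normalization, "initial_epoch")
  # linear decay 2 -> 1 V over the record: starts ~1, ends ~0.5
  n <- fs * 2400
  ramp <- photometry_trace(seq(2, 1, length.out = n), fs)
  nr <- normalize_to_initial(ramp)
  expect_lt(abs(nr$v[1] - 1), 0.01)
  expect_lt(abs(nr$v[n] - 0.5), 0.01)
  # double normalization flagged
  expect_error(normalize_to_initial(nr), class = "pressvigor_error_input")
  # scale invariance
  tr <- photometry_trace(1.4 + 0.1 * sin((1:(fs * 60)) / 50), fs)
  a <- normalize_to_initial(tr)
  b <- normalize_to_initial(photometry_trace(3.7 * tr$v, fs))
  expect_equal(a$v, b$v, tolerance = 1e-12)
})

test_that("bleach ratio: saline self-ratio is exactly 1 and bins cover 40 min", {
  s <- clean_session(seed = 2, duration = 2400, press_rate = 0.15)
  tr <- normalize_to_initial(
    simulate_photometry(photom_sim_params(), s, 2400, fs = 50, seed = 1)$trace)
  ref <- suppressWarnings(saline_reference(tr))
  expect_equal(length(ref), 20)          # 2400 s / 120 s
  r <- bleaching_ratio(tr, ref)
  expect_equal(r$ratio, rep(1, 20))
  # cohort-mean reference: the mean saline ratio is 1 in every bin
  trs <- lapply(1:3, function(i) normalize_to_initial(
    simulate_photometry(photom_sim_params(), s, 2400, fs = 50, seed = i)$trace))
  ref3 <- saline_reference(trs)
  ratios <- vapply(trs, function(t) bleaching_ratio(t, ref3)$ratio,
                   numeric(20))
  expect_equal(rowMeans(ratios), rep(1, 20), tolerance = 1e-12)
  # duration mismatch beyond one bin
  short <- normalize_to_initial(
    simulate_photometry(photom_sim_params(), s, 1200, fs = 50, seed = 9)$trace)
  expect_error(bleaching_ratio(short, ref), class = "pressvigor_error_input")
})

test_that("bleach ratio recovers condition tonic gains in steady-state bins", {
  s <- clean_session(seed = 5, duration = 1800, press_rate = 0.15)
  mk <- function(cond, sd) normalize_to_initial(
    simulate_photometry(photom_sim_params(condition = cond), s, 1800,
                        fs = 50, seed = sd)$trace)
  ref <- saline_reference(lapply(1:3, function(i) mk("saline", i)))
  rl <- bleaching_ratio(mk("levodopa", 11), ref)
  rr <- bleaching_ratio(mk("raclopride", 12), ref)
  steady <- rl$bin_start >= 600    # past the drug-uptake ramp
  expect_true(all(abs(rl$ratio[steady] - 1.5) < 0.05))
  expect_true(all(abs(rr$ratio[steady] - 0.8) < 0.05))
})

test_that("event-triggered averaging recovers injected kernels and drops edge events", {
  fs <- 1000
  z <- photometry_trace(rep(0, fs * 30), fs)
  ev <- c(5, 10, 15)
  eta <- event_triggered_average(z, ev, window = c(1, 2))
  expect_true(all(eta$mean == 0) && all(eta$sem == 0))
  expect_equal(length(eta$mean), length(eta$time))
  # single event: the mean is that snippet
  x <- rnorm(fs * 30, 0, 0.01)
  tr <- photometry_trace(x, fs)
  e1 <- event_triggered_average(tr, 12, window = c(0.5, 0.5))
  expect_equal(as.numeric(e1$snippets[1, ]), e1$mean)
  expect_equal(e1$n_events, 1)
  # events near the record edge are dropped and counted
  e2 <- event_triggered_average(tr, c(0.2, 12, 29.9), window = c(1, 2))
  expect_equal(e2$n_events, 1)
  expect_equal(e2$n_dropped, 2)
  expect_error(event_triggered_average(tr, c(0.1, 29.99), window = c(1, 2)),
               class = "pressvigor_error_input")
  # kernel recovery under noise
  k <- exp(-(0:799) / 250) - exp(-(0:799) / 80); k <- 0.05 * k / max(k)
  ev50 <- seq(3, 3 + 49 * 2.1, by = 2.1)
  x3 <- rnorm(fs * 110, 0, 0.01)
  for (tt in ev50) { i0 <- round(tt * fs) + 1; x3[i0:(i0 + 799)] <- x3[i0:(i0 + 799)] + k }
  e3 <- event_triggered_average(photometry_trace(x3, fs), ev50, window = c(0.5, 1.2))
  rec <- e3$mean[e3$time >= 0 & e3$time < 0.8]
  expect_gt(cor(rec, k), 0.95)
  expect_lte(abs(which.max(rec) - which.max(k)) / fs, 0.05)
})

test_that("press-locked signal sampling marks out-of-span timepoints missing", {
  fs <- 1000
  tr <- photometry_trace(rep(1.3, fs * 20), fs)
  presses <- data.frame(onset_s = c(0.2, 5, 10), t_peak_velocity_s = c(0.26, 5.06, 10.06))
  v <- signal_at_press_timepoints(tr, presses, pre = 0.5)
  expect_true(is.na(v$pre_onset[1]))     # press at t < 0.5 s
  expect_equal(v$onset[2], 1.3)
  expect_equal(v$pre_onset[3], v$peak_velocity[3])   # constant trace
  # injected dip at peak-velocity times shows up as value(peak) < value(-0.5 s)
  x <- rep(1.3, fs * 20)
  for (tt in c(5.06, 10.06)) {
    i0 <- round(tt * fs) + 1
    x[(i0 - 40):(i0 + 40)] <- x[(i0 - 40):(i0 + 40)] - 0.05
  }
  v2 <- signal_at_press_timepoints(photometry_trace(x, fs), presses[-1, ], pre = 0.5)
  expect_true(all(v2$peak_velocity < v2$pre_onset))
})

test_that("blanking and inpainting repairs pulse artifacts without touching other samples", {
  fs <- 2000; n <- fs * 20
  base <- 1.4 - (1:n) / n * 0.1 + 0.01 * sin(2 * pi * 0.5 * (1:n) / fs)
  pulses <- as.numeric(sapply(c(4, 9, 14), function(s) s + (0:29) / 30))
  art <- numeric(n)
  for (tt in pulses) {
    i0 <- round(tt * fs) + 1
    w <- round(0.002 * fs)
    idx <- i0:(i0 + w)
    art[idx] <- art[idx] + 0.05 * (1 - abs(seq(-1, 1, length.out = length(idx))))
  }
  dirty <- photometry_trace(base + art, fs)
  fixed <- blank_and_inpaint(dirty, pulses)
  rmse0 <- sqrt(mean((dirty$v - base)^2))
  rmse1 <- sqrt(mean((fixed$v - base)^2))
  expect_gt(1 - rmse1 / rmse0, 0.9)
  mask <- rep(FALSE, n)
  for (tt in pulses) {
    c0 <- round(tt * fs) + 1
    mask[max(1, c0 - 12):min(n, c0 + 12)] <- TRUE
  }
  expect_identical(fixed$v[!mask], dirty$v[!mask])
  # identity with no pulses; one-sided fill at the record edge
  expect_identical(blank_and_inpaint(dirty, numeric(0)), dirty)
  edge <- blank_and_inpaint(photometry_trace(base, fs), 0)
  expect_equal(length(edge$v), n)
  # refuse to blank the majority of the record
  expect_error(blank_and_inpaint(photometry_trace(base[1:100], fs),
                                 seq(0, 0.05, by = 0.001)),
               class = "pressvigor_error_input")
})

test_that("transient amplitudes recover injected peaks and are ~0 at control times", {
  fs <- 1000
  flat <- photometry_trace(rep(1, fs * 60), fs)
  expect_equal(transient_amplitude(flat, c(10, 20)), c(0, 0))
  k <- exp(-(0:599) / 200) - exp(-(0:599) / 60); k <- 0.05 * k / max(k)
  ev <- seq(5, 50, by = 3)
  x <- rnorm(fs * 60, 0, 0.002)
  for (tt in ev) { i0 <- round(tt * fs) + 1; x[i0:(i0 + 599)] <- x[i0:(i0 + 599)] + k }
  x <- butter_zerophase(x, fs, 30, 10)   # analyses run on filtered traces
  tr <- photometry_trace(x, fs)
  ta <- transient_amplitude(tr, ev, c(-0.3, 0), c(0, 0.5))
  expect_lt(abs(mean(ta) - 0.05), 0.01)
  ctrl <- transient_amplitude(tr, ev - 1.4, c(-0.3, 0), c(0, 0.5))
  expect_lt(abs(mean(ctrl)), 0.015)
  expect_error(transient_amplitude(tr, ev, c(-0.1, 0.2), c(0, 0.5)),
               class = "pressvigor_error_input")
  # events outside the record are NA, not errors
  expect_true(is.na(transient_amplitude(tr, 59.9, c(-0.3, 0), c(0, 0.5))))
})
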