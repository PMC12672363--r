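#' Generate a single ballistic press waveform
#'
#' Deterministic raised-cosine (Hann) velocity-pulse press: the inward phase
#' has velocity `v(t) = Vp * sin^2(pi t / T)` with duration `T = 2 A / Vp`
#' solved from the requested amplitude `A` and peak velocity `Vp`, giving the
#' closed-form position `x(t) = A (t/T - sin(2 pi t / T) / (2 pi))`. The
#' return phase is a slower raised-cosine back to rest (outward, so it never
#' affects inward kinematics). The maximum displacement equals `A` and the
#' maximum instantaneous velocity equals `Vp` up to sample quantization.
#'
#' @param amplitude press amplitude (mm), > 0.
#' @param peak_velocity peak inward velocity (mm/s), > 0.
#' @param onset press onset time (s), snapped to the sample grid.
#' @param fs sampling rate (Hz).
#' @param return_factor return-phase duration as a multiple of the inward
#'   duration.
#' @return A list with `i0` (0-based onset sample), `x` (position segment,
#'   mm), `t_peak` (time of peak inward velocity, s) and `duration` (s).
#' @export
simulate_press_waveform <- function(amplitude, peak_velocity, onset = 0,
                                    fs = 1000, return_factor = 2) {
  if (!(amplitude > 0))
    stop_pv("pressvigor_error_param", "amplitude must be > 0")
  if (!(peak_velocity > 0))
    stop_pv("pressvigor_error_param", "peak_velocity must be > 0")
  if (!(fs > 0)) stop_pv("pressvigor_error_param", "fs must be > 0")
  T_in <- 2 * amplitude / peak_velocity
  if (T_in * fs < 8)
    stop_pv("pressvigor_error_param", sprintf(
      "infeasible (amplitude, peak_velocity): pulse duration 2A/Vp = %.4g s is below the %g-sample resolvability bound at fs = %g Hz (need peak_velocity <= %.4g mm/s for this amplitude)",
      T_in, 8, fs, 2 * amplitude * fs / 8))
  i0 <- round(onset * fs)
  n_in <- round(T_in * fs)
  t_in <- (0:n_in) / fs
  x_in <- amplitude * (t_in / T_in - sin(2 * pi * t_in / T_in) / (2 * pi))
  x_in[length(x_in)] <- amplitude
  T_ret <- return_factor * T_in
  n_ret <- round(T_ret * fs)
  t_ret <- (1:n_ret) / fs
  x_ret <- amplitude * cos(pi * t_ret / (2 * T_ret))^2
  x_ret[length(x_ret)] <- 0
  list(i0 = i0, x = c(x_in, x_ret), t_peak = i0 / fs + T_in / 2,
       duration = T_in + T_ret)
}

# Let-go release: replaces the smooth return. From the peak, the lever shoots
# back through rest to a fixed -overshoot_mm outward excursion in ~20 ms, then
# rings as a damped oscillation (freq_hz, per-half-cycle decay `decay_ratio`).
# The first inward rebound is overshoot_mm * decay_ratio, kept below the
# press threshold so the ringing never registers as a new press, while its
# high inward velocity contaminates the press window unless the >2.5 mm
# overshoot exclusion rule is applied.
letgo_release <- function(amplitude, fs, overshoot_mm = 4.0, freq_hz = 18,
                          decay_ratio = 0.35, drop_duration = 0.03) {
  n_drop <- max(2, round(drop_duration * fs))
  t_drop <- (1:n_drop) / fs
  Td <- n_drop / fs
  x_drop <- -overshoot_mm + (amplitude + overshoot_mm) *
    cos(pi * t_drop / (2 * Td))^2
  lambda <- -log(decay_ratio) / (1 / (2 * freq_hz))
  n_osc <- ceiling(log(0.02 / overshoot_mm) / -lambda * fs)
  t_osc <- (1:n_osc) / fs
  x_osc <- -overshoot_mm * exp(-lambda * t_osc) * cos(2 * pi * freq_hz * t_osc)
  c(x_drop, x_osc, 0)
}

# Small postural micro-adjustment: Hann position blip below the press
# threshold.
microadjust_waveform <- function(amplitude, duration, fs) {
  n <- max(4, round(duration * fs))
  t <- (0:n) / n
  amplitude * sin(pi * t)^2
}
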