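#' Photometry simulation parameters
#'
#' Component model of the photoreceiver voltage:
#' `F(t) = dark + autofluorescence + B(t) * (F_unbound + tonic(t) + phasic(t)) + noise`,
#' where `B(t)` is a monotonically decreasing double-exponential bleach
#' factor, `tonic(t)` is the ambient-dopamine (DA) contribution scaled by a
#' per-condition gain that ramps in over the first minutes of the recording
#' (drug uptake), and `phasic(t)` is the sum of reward-locked and spontaneous
#' subsecond DA transients whose energy falls in the 0.5-4 Hz band.
#'
#' Condition structure: relative to saline, levodopa raises the tonic gain
#' without adding phasic events; raclopride lowers the tonic gain and scales
#' transient amplitudes down; a complete mDAN lesion removes both the tonic DA
#' contribution and all phasic transients. The defaults put the starting
#' voltage (~1.4 V) inside the empirically observed 0.7-2.0 V range, with
#' dark current and patch-cord autofluorescence minor (pre-bleached cords) so
#' that the signal is dominated by DA-bound sensor fluorescence.
#'
#' @param dark_offset photoreceiver dark voltage (V).
#' @param autofluorescence patch-cord/brain autofluorescence (V).
#' @param f_unbound DA-independent sensor fluorescence (V).
#' @param tonic_level DA-bound sensor fluorescence under saline (V).
#' @param tonic_gain named per-condition multipliers of `tonic_level`.
#' @param phasic_gain named per-condition multipliers of transient amplitudes.
#' @param bleach_timeconstants two time constants (s) of the bleach factor.
#' @param bleach_weights weights of the two exponentials (sum 1); the long
#'   time constant dominates, giving near-linear loss over 40 min.
#' @param drug_ramp time (s) over which the condition gain reaches its
#'   plateau (smoothstep ramp); lesions apply from t = 0.
#' @param phasic_band frequency band (Hz) where transient energy falls.
#' @param reward_kernel list with `amplitude` (V), `rise` (s), `decay` (s),
#'   `latency` (s): the biexponential reward transient.
#' @param spontaneous_transient_rate Poisson rate of spontaneous transients
#'   (events/s).
#' @param spontaneous_amplitude log-normal `meanlog`/`sdlog` of spontaneous
#'   transient amplitudes (V).
#' @param noise_sd white measurement noise s.d. (V).
#' @param condition condition label.
#' @return An object of class `photom_sim_params`.
#' @export
photom_sim_params <- function(dark_offset = 0.005,
                              autofluorescence = 0.02,
                              f_unbound = 0.055,
                              tonic_level = 1.32,
                              tonic_gain = c(saline = 1.0, raclopride = 0.8,
                                             levodopa = 1.5, lesion = 0.0),
                              phasic_gain = c(saline = 1.0, raclopride = 0.5,
                                              levodopa = 1.0, lesion = 0.0),
                              bleach_timeconstants = c(60, 6000),
                              bleach_weights = c(0.05, 0.95),
                              drug_ramp = 300,
                              phasic_band = c(0.5, 4),
                              reward_kernel = list(amplitude = 0.04,
                                                   rise = 0.08, decay = 0.25,
                                                   latency = 0.05),
                              spontaneous_transient_rate = 1.2,
                              spontaneous_amplitude = c(meanlog = log(0.04),
                                                        sdlog = 0.4),
                              noise_sd = 0.005,
                              condition = "saline") {
  stopifnot(condition %in% names(tonic_gain),
            all(tonic_gain >= 0), all(phasic_gain >= 0),
            spontaneous_transient_rate >= 0, noise_sd >= 0,
            all(bleach_timeconstants > 0),
            abs(sum(bleach_weights) - 1) < 1e-9)
  if (tonic_gain[["lesion"]] != 0 || phasic_gain[["lesion"]] != 0)
    stop_pv("pressvigor_error_config",
            "lesion condition must have zero tonic gain and zero phasic gain")
  structure(as.list(environment()), class = "photom_sim_params")
}

#' Optogenetic stimulation schedule parameters
#'
#' Stimulation is applied at uncued trial start on a pseudo-random ~30%
#' subset of trials from `start_trial` onward, as 10-ms pulses at 30 Hz for
#' `train_duration` seconds; each pulse leaves a brief additive light
#' artifact on the photometry channel.
#'
#' @param fraction fraction of eligible trials stimulated.
#' @param start_trial first eligible trial.
#' @param pulse_rate pulse rate within a train (Hz).
#' @param pulse_width single pulse width (s).
#' @param train_duration train duration (s).
#' @param artifact_amplitude peak artifact amplitude (V).
#' @param artifact_width artifact width on the photometry channel (s); kept
#'   inside the +/-6 ms blanking window used for repair.
#' @return An object of class `opto_sim_params`.
#' @export
opto_sim_params <- function(fraction = 0.3, start_trial = 11,
                            pulse_rate = 30, pulse_width = 0.010,
                            train_duration = 1.0,
                            artifact_amplitude = 0.05,
                            artifact_width = 0.004) {
  stopifnot(fraction >= 0, fraction <= 1, start_trial >= 1,
            pulse_rate > 0, train_duration > 0, artifact_amplitude >= 0)
  structure(as.list(environment()), class = "opto_sim_params")
}

#' Synthetic-session configuration
#'
#' Generator defaults emulate the study conditions: ~30-min sessions of
#' self-paced ballistic presses every few seconds, log-normal amplitudes
#' straddling the press (1.7 mm) and reward (4.1 mm) thresholds such that
#' roughly two-thirds of presses are rewarded, occasional let-go oscillation
#' artifacts, postural micro-adjustments below the press threshold, and
#' encoder noise.
#'
#' @param seed integer seed; every simulation output is a pure function of
#'   (`sim_config`, `task_config`).
#' @param session_duration session length (s).
#' @param press_rate press initiations per second (inter-press intervals are
#'   exponential with a refractory minimum gap; the distribution family is
#'   deliberately exposed here rather than fixed by the analysis).
#' @param amplitude_dist log-normal `meanlog`/`sdlog` of press amplitude (mm).
#' @param peak_velocity_dist log-normal `meanlog`/`sdlog` of press peak
#'   velocity (mm/s). Draws are clipped into `[4A, 40A]` for amplitude `A` so
#'   the raised-cosine pulse family stays feasible (press duration
#'   0.05-0.5 s).
#' @param letgo_prob probability that a press ends in a let-go oscillation.
#' @param microadjust_rate rate of postural micro-adjustments (events/s).
#' @param lever_noise_sd encoder noise s.d. (mm).
#' @param fs lever sampling rate of the generated trace (Hz).
#' @param min_gap refractory minimum onset-to-onset gap (s).
#' @param photometry a [photom_sim_params()].
#' @param opto an [opto_sim_params()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       session_duration = 1800,
                       press_rate = 0.25,
                       amplitude_dist = c(meanlog = log(4.8), sdlog = 0.4),
                       peak_velocity_dist = c(meanlog = log(85), sdlog = 0.35),
                       letgo_prob = 0.05,
                       microadjust_rate = 0.1,
                       lever_noise_sd = 0.02,
                       fs = 1000,
                       min_gap = 2.5,
                       photometry = photom_sim_params(),
                       opto = opto_sim_params()) {
  stopifnot(session_duration > 0, press_rate >= 0,
            letgo_prob >= 0, letgo_prob <= 1,
            microadjust_rate >= 0, lever_noise_sd >= 0, fs > 0, min_gap > 0)
  # amplitude support must straddle both press classes
  q <- exp(amplitude_dist[["meanlog"]] +
           c(-2, 2) * amplitude_dist[["sdlog"]])
  if (!(q[1] < 4.1 && q[2] > 4.1))
    stop_pv("pressvigor_error_config",
            "amplitude distribution must straddle the press and reward thresholds")
  structure(as.list(environment()), class = "sim_config")
}
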