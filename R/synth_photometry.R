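biexp_kernel <- function(fs, rise, decay, length_s = NULL) {
  if (is.null(length_s)) length_s <- decay * 6
  t <- seq(0, length_s, by = 1 / fs)
  h <- exp(-t / decay) - exp(-t / rise)
  h / max(h)
}

smoothstep01 <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Simulate a photometry recording with component-level ground truth
#'
#' Composes the photoreceiver voltage as
#' `F(t) = dark + autofluorescence + B(t) * (F_unbound + tonic(t) + phasic(t))
#' + artifact(t) + noise`, with `B(t)` the double-exponential bleach factor,
#' `tonic(t)` the ambient-DA sensor fluorescence under the condition's gain
#' (ramping in smoothly over `drug_ramp` seconds for drug conditions, zero
#' throughout for lesions), `phasic(t)` the sum of reward-locked and
#' spontaneous biexponential DA transients, and `artifact(t)` brief additive
#' light spikes at optogenetic pulse times. Every component is returned
#' per-sample so the emitted trace can be reconstructed exactly.
#'
#' @param p a [photom_sim_params()].
#' @param events reward/pulse times: either a `trial_log`, a
#'   `synthetic_session`, or a list with `reward_times` and optionally
#'   `pulse_times` (s).
#' @param duration recording duration (s).
#' @param fs sampling rate (Hz); the acquisition hardware digitizes at
#'   2 kHz, lower rates are adequate for the <= 11 Hz analyses.
#' @param seed integer seed for transient times and noise.
#' @return A list with `trace` (a [photometry_trace()]) and `components`
#'   (data.frame: offset, bleach, tonic_v, phasic_v, artifact, noise; the
#'   row sums of offset + tonic_v + phasic_v + artifact + noise equal the
#'   trace exactly).
#' @export
simulate_photometry <- function(p, events = list(reward_times = numeric(0)),
                                duration = 1800, fs = 250, seed = 1L) {
  stopifnot(inherits(p, "photom_sim_params"), duration > 0, fs > 0)
  if (inherits(events, "synthetic_session"))
    events <- list(reward_times = events$truth$reward_times,
                   pulse_times = events$truth$pulse_times)
  if (inherits(events, "trial_log"))
    events <- list(
      reward_times = events$trials$reward_time[events$trials$outcome == "rewarded"],
      pulse_times = numeric(0))
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs

  B <- p$bleach_weights[1] * exp(-t / p$bleach_timeconstants[1]) +
       p$bleach_weights[2] * exp(-t / p$bleach_timeconstants[2])

  g_target <- p$tonic_gain[[p$condition]]
  gain_t <- if (p$condition == "lesion") rep(0, n)
            else if (p$condition == "saline") rep(1, n)
            else 1 + (g_target - 1) * smoothstep01(t / p$drug_ramp)
  tonic <- gain_t * p$tonic_level

  pg <- p$phasic_gain[[p$condition]]
  phasic <- numeric(n)
  if (pg > 0) {
    k_rew <- biexp_kernel(fs, p$reward_kernel$rise, p$reward_kernel$decay)
    rt <- events$reward_times
    rt <- rt[is.finite(rt)]
    for (tt in rt) {
      i0 <- round((tt + p$reward_kernel$latency) * fs) + 1
      idx <- i0 + seq_along(k_rew) - 1
      keep <- idx >= 1 & idx <= n
      phasic[idx[keep]] <- phasic[idx[keep]] +
        pg * p$reward_kernel$amplitude * k_rew[keep]
    }
    spont <- with_seed(sub_seed(seed, 11), {
      ns <- rpois(1, p$spontaneous_transient_rate * duration)
      list(times = sort(runif(ns, 0, duration)),
           amps = rlnorm(ns, p$spontaneous_amplitude[["meanlog"]],
                         p$spontaneous_amplitude[["sdlog"]]))
    })
    k_sp <- biexp_kernel(fs, 0.06, 0.18)
    spont_tr <- numeric(n)
    for (j in seq_along(spont$times)) {
      i0 <- round(spont$times[j] * fs) + 1
      idx <- i0 + seq_along(k_sp) - 1
      keep <- idx >= 1 & idx <= n
      spont_tr[idx[keep]] <- spont_tr[idx[keep]] + pg * spont$amps[j] * k_sp[keep]
    }
    # spontaneous transient energy is band-limited to the phasic band
    if (any(spont_tr != 0)) {
      bf <- signal::butter(2, 2 * p$phasic_band / fs, type = "pass")
      spont_tr <- as.numeric(signal::filtfilt(bf, spont_tr))
    }
    phasic <- phasic + spont_tr
  }

  artifact <- numeric(n)
  pt <- events$pulse_times
  if (!is.null(pt) && length(pt) && p$condition != "none") {
    hw <- max(1, round(0.004 / 2 * fs))
    spike <- 0.05 * c(seq(0, 1, length.out = hw + 1),
                      seq(1, 0, length.out = hw + 1)[-1])
    # amplitude taken from the opto schedule owner; here a fixed shape scaled
    # by the configured artifact amplitude stored alongside pulse times
    amp <- attr(pt, "artifact_amplitude")
    if (is.null(amp)) amp <- 0.05
    spike <- spike / max(spike) * amp
    for (tt in pt) {
      i0 <- round(tt * fs) + 1
      idx <- i0 + seq_along(spike) - 1
      keep <- idx >= 1 & idx <= n
      artifact[idx[keep]] <- artifact[idx[keep]] + spike[keep]
    }
  }

  noise <- if (p$noise_sd > 0)
    with_seed(sub_seed(seed, 12), rnorm(n, 0, p$noise_sd))
  else numeric(n)

  offset <- p$dark_offset + p$autofluorescence
  tonic_v <- B * (p$f_unbound + tonic)
  phasic_v <- B * phasic
  v <- offset + tonic_v + phasic_v + artifact + noise
  if (min(v) < 0)
    stop_pv("pressvigor_error_config",
            "composed fluorescence is negative; check simulation parameters")

  comp <- data.frame(offset = rep(offset, n), bleach = B,
                     tonic_v = tonic_v, phasic_v = phasic_v,
                     artifact = artifact, noise = noise)
  trace <- photometry_trace(v, fs, condition = p$condition)
  list(trace = trace, components = comp)
}
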