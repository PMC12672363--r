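# shared fixtures, built in code at test time

# a short clean session: no micro-adjustments, no encoder noise, so that
# event-level replays and exact comparisons hold
clean_session <- function(seed = 1, duration = 120, fs = 1000, ...) {
  simulate_session(
    sim_config(seed = seed, session_duration = duration, fs = fs,
               microadjust_rate = 0, lever_noise_sd = 0, ...),
    task_config())
}

# scripted lever trace: hold at rest, then a linear ramp press to `amp` mm
# peaking `ramp_s` seconds after leaving rest, then return
scripted_press_trace <- function(hold_s = 0.4, ramp_s = 0.08, amp = 5,
                                 fs = 1000, total_s = 3) {
  x <- rep(0, total_s * fs)
  n_ramp <- round(ramp_s * fs)
  i0 <- round(hold_s * fs) + 1
  x[i0:(i0 + n_ramp - 1)] <- seq(0, amp, length.out = n_ramp)
  x[(i0 + n_ramp):(i0 + 2 * n_ramp - 1)] <- seq(amp, 0, length.out = n_ramp)
  lever_trace(x, fs)
}

# synthesize 1/f^slope noise by spectral shaping (known PSD slope oracle)
powerlaw_noise <- function(n, fs, slope, seed = 1) {
  with_seed <- get("with_seed", asNamespace("pressvigor"))
  with_seed(seed, {
    nf <- floor(n / 2)
    f <- (1:nf) * fs / n
    mag <- f^(-slope / 2)
    ph <- runif(nf, 0, 2 * pi)
    spec <- complex(modulus = mag, argument = ph)
    full <- c(0, spec, rev(Conj(spec[if (n %% 2 == 0) -nf else TRUE])))
    Re(fft(full, inverse = TRUE)) / n
  })
}
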