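#' Zero-phase Butterworth low-pass filtering
#'
#' Applies an order-`poles/2` digital Butterworth design forward and backward
#' (`signal::filtfilt`), giving a zero-phase response with `poles` poles in
#' total and squared magnitude `1 / (1 + (f/fc)^poles)`.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param cutoff cutoff frequency (Hz).
#' @param poles total pole count (even).
#' @return Filtered vector of the same length.
#' @export
butter_zerophase <- function(x, fs, cutoff, poles) {
  stopifnot(poles %% 2 == 0, cutoff > 0, cutoff < fs / 2)
  bf <- signal::butter(poles / 2, 2 * cutoff / fs, type = "low")
  # odd-reflection padding suppresses the forward-backward edge transients
  n <- length(x)
  npad <- min(n - 1, max(32, ceiling(3 * fs / cutoff)))
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(npad + 1):(npad + n)]
}

#' Analytic magnitude response of the zero-phase Butterworth cascade
#'
#' The forward-backward cascade of an order-`poles/2` Butterworth filter has
#' magnitude `1 / (1 + (f/fc)^poles)`. This closed form is the oracle used to
#' validate the preprocessing stages.
#'
#' @param f frequency (Hz), vectorized.
#' @param cutoff cutoff frequency (Hz).
#' @param poles total pole count of the cascade.
#' @return Magnitude gain in (0, 1].
#' @export
butter_zerophase_gain <- function(f, cutoff, poles) {
  1 / (1 + (f / cutoff)^poles)
}

# anti-aliased integer-factor decimation: zero-phase Butterworth at
# 0.45 * target Nyquist-band edge, then subsampling
decimate_series <- function(x, fs_in, fs_out) {
  q <- fs_in / fs_out
  if (abs(q - round(q)) > 1e-9)
    stop_pv("pressvigor_error_format",
            sprintf("fs_in (%g) must be an integer multiple of fs_out (%g)",
                    fs_in, fs_out))
  q <- round(q)
  if (q == 1) return(x)
  y <- butter_zerophase(x, fs_in, cutoff = 0.45 * fs_out, poles = 8)
  y[seq(1, length(y), by = q)]
}

#' Preprocess a raw lever trace for kinematic analysis
#'
#' Anti-aliased decimation of the acquisition-rate position signal (nominally
#' digitized at 10 kHz) to 1 kHz, followed by a zero-phase 30 Hz low-pass with
#' 6 poles in total.
#'
#' @param raw a [lever_trace()] or numeric vector of positions (mm).
#' @param fs_in input sampling rate (Hz); taken from the trace if omitted.
#'   Must be >= 2000 Hz.
#' @param fs_out output rate (Hz), default 1000.
#' @param cutoff low-pass cutoff (Hz), default 30.
#' @param poles total pole count, default 6.
#' @return A [lever_trace()] at `fs_out` with filtering recorded in
#'   `provenance`.
#' @export
preprocess_lever <- function(raw, fs_in = NULL, fs_out = 1000, cutoff = 30,
                             poles = 6) {
  if (inherits(raw, "lever_trace")) {
    fs_in <- raw$fs; t0 <- raw$t0; x <- raw$position
    prov <- raw$provenance
  } else {
    stopifnot(!is.null(fs_in)); t0 <- 0; x <- as.numeric(raw); prov <- list()
  }
  if (fs_in < 2 * fs_out)
    stop_pv("pressvigor_error_format",
            sprintf("fs_in = %g Hz: need >= %g Hz to decimate to %g Hz",
                    fs_in, 2 * fs_out, fs_out))
  y <- decimate_series(x, fs_in, fs_out)
  y <- butter_zerophase(y, fs_out, cutoff, poles)
  prov$filter <- sprintf("decimated %g->%g Hz; zero-phase Butterworth %g Hz, %d poles",
                         fs_in, fs_out, cutoff, poles)
  lever_trace(y, fs_out, t0 = t0, provenance = prov)
}

#' Preprocess a raw photometry trace
#'
#' Decimates the photoreceiver voltage (nominally digitized at 2 kHz) to
#' 1 kHz and applies a zero-phase 30 Hz low-pass with 10 poles in total.
#'
#' @param raw a [photometry_trace()] or numeric vector of voltages (V).
#' @param fs_in input sampling rate (Hz); taken from the trace if omitted.
#'   Must be >= 2000 Hz.
#' @param fs_out output rate (Hz), default 1000.
#' @param cutoff low-pass cutoff (Hz), default 30.
#' @param poles total pole count, default 10.
#' @return A [photometry_trace()] at `fs_out`.
#' @export
preprocess_photometry <- function(raw, fs_in = 2000, fs_out = 1000,
                                  cutoff = 30, poles = 10) {
  if (inherits(raw, "photometry_trace")) {
    fs_in <- raw$fs; t0 <- raw$t0; v <- raw$v
    condition <- raw$condition; norm <- raw$normalization; f0 <- raw$F0_estimate
  } else {
    t0 <- 0; v <- as.numeric(raw); condition <- "saline"; norm <- "raw"
    f0 <- NA_real_
  }
  if (fs_in < 2 * fs_out)
    stop_pv("pressvigor_error_format",
            sprintf("fs_in = %g Hz: need >= %g Hz to decimate to %g Hz",
                    fs_in, 2 * fs_out, fs_out))
  y <- decimate_series(v, fs_in, fs_out)
  y <- butter_zerophase(y, fs_out, cutoff, poles)
  photometry_trace(y, fs_out, t0 = t0, condition = condition,
                   normalization = norm, F0_estimate = f0)
}
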