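#' Lever position trace
#'
#' Container for a uniformly sampled lever-position series. Positions are in
#' mm with the rewarded (inward) direction positive; the rest position is 0.
#'
#' @param position numeric vector of positions (mm).
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample (s).
#' @param provenance named list recording how the trace was produced
#'   (e.g. sign convention, filtering applied).
#' @return An object of class `lever_trace`.
#' @export
lever_trace <- function(position, fs, t0 = 0, provenance = list()) {
  stopifnot(is.numeric(position), length(position) > 0, fs > 0)
  structure(list(position = as.numeric(position), fs = fs, t0 = t0,
                 provenance = provenance),
            class = "lever_trace")
}

#' @export
print.lever_trace <- function(x, ...) {
  cat(sprintf("<lever_trace> %d samples @ %g Hz (%.1f s), range [%.2f, %.2f] mm\n",
              length(x$position), x$fs, length(x$position) / x$fs,
              min(x$position), max(x$position)))
  invisible(x)
}

#' Photometry fluorescence trace
#'
#' Container for a uniformly sampled photoreceiver voltage series, with the
#' pharmacological condition label and a record of any normalization applied.
#' `F0_estimate` holds the global baseline fluorescence (the mean over the
#' initial epoch) once [normalize_to_initial()] has run.
#'
#' @param v numeric vector of voltages (V; dimensionless after normalization).
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample (s).
#' @param condition condition label, one of `"saline"`, `"raclopride"`,
#'   `"levodopa"`, `"lesion"` or any user label.
#' @param normalization `"raw"` or `"initial_epoch"`.
#' @param F0_estimate baseline fluorescence estimate (V), `NA` until computed.
#' @return An object of class `photometry_trace`.
#' @export
photometry_trace <- function(v, fs, t0 = 0, condition = "saline",
                             normalization = "raw", F0_estimate = NA_real_) {
  stopifnot(is.numeric(v), length(v) > 0, fs > 0)
  structure(list(v = as.numeric(v), fs = fs, t0 = t0, condition = condition,
                 normalization = normalization, F0_estimate = F0_estimate),
            class = "photometry_trace")
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("<photometry_trace> %d samples @ %g Hz (%.1f s), condition %s, %s\n",
              length(x$v), x$fs, length(x$v) / x$fs, x$condition,
              x$normalization))
  invisible(x)
}

trace_times <- function(trace) {
  n <- if (inherits(trace, "lever_trace")) length(trace$position) else length(trace$v)
  trace$t0 + (seq_len(n) - 1) / trace$fs
}

trace_values <- function(trace) {
  if (inherits(trace, "lever_trace")) trace$position else trace$v
}
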