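#' Normalize a photometry trace to its initial epoch
#'
#' Divides the trace by the mean voltage of its first `epoch` seconds, so
#' recordings can be compared within and between animals across days. The
#' epoch mean is stored as the baseline-fluorescence estimate (F0). Applying
#' the normalization twice is an error (the normalization record guards it).
#'
#' @param trace a [photometry_trace()].
#' @param epoch initial epoch length (s), default 15.
#' @return The normalized [photometry_trace()] (starts at ~1 over the epoch).
#' @export
normalize_to_initial <- function(trace, epoch = 15) {
  stopifnot(inherits(trace, "photometry_trace"))
  if (trace$normalization != "raw")
    stop_pv("pressvigor_error_input",
            "trace is already initial-epoch normalized")
  n_ep <- round(epoch * trace$fs)
  if (length(trace$v) <= n_ep)
    stop_pv("pressvigor_error_input", "trace shorter than the initial epoch")
  f0 <- mean(trace$v[seq_len(n_ep)])
  if (!is.finite(f0) || f0 <= 0)
    stop_pv("pressvigor_error_input", "non-positive initial-epoch mean")
  photometry_trace(trace$v / f0, trace$fs, t0 = trace$t0,
                   condition = trace$condition,
                   normalization = "initial_epoch", F0_estimate = f0)
}

bin_means <- function(trace, bin) {
  n_bin <- round(bin * trace$fs)
  k <- floor(length(trace$v) / n_bin)
  if (k < 1) stop_pv("pressvigor_error_input", "trace shorter than one bin")
  vapply(seq_len(k), function(j)
    mean(trace$v[((j - 1) * n_bin + 1):(j * n_bin)]), numeric(1))
}

#' Per-bin saline reference for bleach-ratio correction
#'
#' Mean of the binned, normalized voltages across one or more saline
#' recordings of the cohort. With a single recording a warning notes the
#' single-session reference.
#'
#' @param traces a [photometry_trace()] or list of them (normalized).
#' @param bin bin width (s), default 120.
#' @return Numeric vector of per-bin reference means.
#' @export
saline_reference <- function(traces, bin = 120) {
  if (inherits(traces, "photometry_trace")) traces <- list(traces)
  if (length(traces) == 1)
    warning("single-session saline reference")
  for (tr in traces)
    if (tr$normalization != "initial_epoch")
      stop_pv("pressvigor_error_input", "reference traces must be normalized")
  bm <- lapply(traces, bin_means, bin = bin)
  k <- min(lengths(bm))
  rowMeans(vapply(bm, function(b) b[seq_len(k)], numeric(k)))
}

#' Bleach-ratio correction against the saline reference
#'
#' Averages the normalized voltage in `bin`-second bins and divides each bin
#' by the saline-reference mean of the same time bin, removing the shared
#' photobleaching trajectory. By construction the saline reference divided by
#' itself is 1 in every bin; steady-state deviations from 1 estimate the
#' condition's tonic gain on the DA-bound sensor fluorescence.
#'
#' @param test a normalized [photometry_trace()].
#' @param reference a per-bin reference vector from [saline_reference()], or
#'   a normalized trace / list of traces from which to build one.
#' @param bin bin width (s), default 120 (2 min).
#' @return Data frame: `bin_start`, `bin_mid` (s), `ratio`.
#' @export
bleaching_ratio <- function(test, reference, bin = 120) {
  stopifnot(inherits(test, "photometry_trace"))
  if (test$normalization != "initial_epoch")
    stop_pv("pressvigor_error_input", "test trace must be normalized first")
  ref <- if (is.numeric(reference)) reference
         else suppressWarnings(saline_reference(reference, bin))
  tb <- bin_means(test, bin)
  if (abs(length(tb) - length(ref)) > 1)
    stop_pv("pressvigor_error_input",
            sprintf("duration mismatch: test has %d bins, reference %d",
                    length(tb), length(ref)))
  k <- min(length(tb), length(ref))
  data.frame(bin_start = (seq_len(k) - 1) * bin,
             bin_mid = (seq_len(k) - 0.5) * bin,
             ratio = tb[seq_len(k)] / ref[seq_len(k)])
}

#' Event-triggered average of a photometry trace
#'
#' Extracts per-event snippets in a `[-pre, post]` window around each event,
#' and returns the snippet matrix with mean and s.e.m. traces. Events too
#' close to the record edges are dropped and counted.
#'
#' @param trace a [photometry_trace()].
#' @param event_times event times (s).
#' @param window `c(pre, post)` window half-lengths (s), both positive.
#' @return Object of class `event_aligned`: `time`, `snippets` (events x
#'   samples), `mean`, `sem`, `n_events`, `n_dropped`.
#' @export
event_triggered_average <- function(trace, event_times, window = c(1, 2)) {
  stopifnot(inherits(trace, "photometry_trace"), length(window) == 2,
            all(window > 0))
  fs <- trace$fs; n <- length(trace$v)
  pre_n <- round(window[1] * fs); post_n <- round(window[2] * fs)
  centers <- round((event_times - trace$t0) * fs) + 1
  ok <- centers - pre_n >= 1 & centers + post_n <= n & is.finite(centers)
  if (!any(ok))
    stop_pv("pressvigor_error_input", "no events fully inside the trace")
  centers <- centers[ok]
  rel <- -pre_n:post_n
  snip <- t(vapply(centers, function(c0) trace$v[c0 + rel],
                   numeric(length(rel))))
  m <- colMeans(snip)
  s <- if (nrow(snip) > 1) apply(snip, 2, sd) / sqrt(nrow(snip))
       else rep(0, ncol(snip))
  structure(list(time = rel / fs, snippets = snip, mean = m, sem = s,
                 n_events = nrow(snip), n_dropped = sum(!ok)),
            class = "event_aligned")
}

#' @export
print.event_aligned <- function(x, ...) {
  cat(sprintf("<event_aligned> %d events (%d dropped), window [%.2f, %.2f] s\n",
              x$n_events, x$n_dropped, min(x$time), max(x$time)))
  invisible(x)
}

#' Photometry signal at press-locked timepoints
#'
#' For each press, the trace value `pre` seconds before press onset, at press
#' onset, and at the time of peak press velocity. Timepoints outside the
#' record are returned as `NA`.
#'
#' @param trace a [photometry_trace()].
#' @param presses a `press_table` (needs `onset_s` and `t_peak_velocity_s`).
#' @param pre lead time before onset (s); the study uses 0.5-1 s.
#' @return Data frame: `pre_onset`, `onset`, `peak_velocity` values per press.
#' @export
signal_at_press_timepoints <- function(trace, presses, pre = 0.5) {
  stopifnot(inherits(trace, "photometry_trace"))
  at <- function(tt) {
    i <- round((tt - trace$t0) * trace$fs) + 1
    ifelse(i >= 1 & i <= length(trace$v), trace$v[pmin(pmax(i, 1), length(trace$v))],
           NA_real_)
  }
  data.frame(pre_onset = at(presses$onset_s - pre),
             onset = at(presses$onset_s),
             peak_velocity = at(presses$t_peak_velocity_s))
}

#' Blank and inpaint stimulation-locked light artifacts
#'
#' Replaces samples within `halfwidth` of each optogenetic light pulse with
#' values interpolated from the surrounding data (shape-preserving piecewise
#' cubic for interior gaps, linear continuation at record edges). Applied to
#' the raw trace before any filtering. Samples outside the blanked windows
#' are returned bit-identical.
#'
#' @param trace a [photometry_trace()].
#' @param pulse_times pulse times (s), sorted.
#' @param halfwidth half-width of the blanked window around each pulse (s),
#'   default 0.006 (+/-6 ms).
#' @return The repaired [photometry_trace()].
#' @export
blank_and_inpaint <- function(trace, pulse_times, halfwidth = 0.006) {
  stopifnot(inherits(trace, "photometry_trace"))
  if (!length(pulse_times)) return(trace)
  if (is.unsorted(pulse_times))
    stop_pv("pressvigor_error_input", "pulse_times must be sorted")
  fs <- trace$fs; n <- length(trace$v)
  hw_n <- round(halfwidth * fs)
  mask <- rep(FALSE, n)
  for (tt in pulse_times) {
    c0 <- round((tt - trace$t0) * fs) + 1
    lo <- max(1, c0 - hw_n); hi <- min(n, c0 + hw_n)
    if (lo <= hi && c0 + hw_n >= 1 && c0 - hw_n <= n) mask[lo:hi] <- TRUE
  }
  if (mean(mask) > 0.5)
    stop_pv("pressvigor_error_input",
            sprintf("%.0f%% of samples would be blanked", 100 * mean(mask)))
  if (!any(mask)) return(trace)
  v <- trace$v
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    if (a == 1 || b == n) {
      # edge gap: linear continuation from the two nearest good samples
      if (a == 1) {
        if (b + 2 <= n) {
          slope <- v[b + 2] - v[b + 1]
          v[a:b] <- v[b + 1] - slope * ((b + 1) - (a:b))
        } else v[a:b] <- v[min(b + 1, n)]
      } else {
        if (a - 2 >= 1) {
          slope <- v[a - 1] - v[a - 2]
          v[a:b] <- v[a - 1] + slope * ((a:b) - (a - 1))
        } else v[a:b] <- v[a - 1]
      }
    } else {
      ctx <- 20
      lo <- max(1, a - ctx); hi <- min(n, b + ctx)
      good <- setdiff(lo:hi, a:b)
      good <- good[!mask[good]]
      if (length(good) >= 2) {
        v[a:b] <- pracma::pchip(good, v[good], a:b)
      } else {
        v[a:b] <- mean(v[c(a - 1, b + 1)])
      }
    }
  }
  out <- trace
  out$v <- v
  out
}

#' Per-event transient amplitude
#'
#' Peak-minus-baseline amplitude of the signal around each event: the
#' baseline is the mean over `baseline_window` and the peak is the maximum
#' over `peak_window` (both relative to the event time, peak after baseline).
#' Used to calibrate stimulation-evoked transients against reward transients
#' on initial-epoch-normalized traces.
#'
#' @param trace a [photometry_trace()].
#' @param event_times event times (s).
#' @param baseline_window `c(lo, hi)` relative window for the baseline (s).
#' @param peak_window `c(lo, hi)` relative window for the peak (s).
#' @return Numeric vector of per-event amplitudes (`NA` where a window falls
#'   outside the record).
#' @export
transient_amplitude <- function(trace, event_times,
                                baseline_window = c(-0.5, 0),
                                peak_window = c(0, 1)) {
  stopifnot(inherits(trace, "photometry_trace"))
  if (baseline_window[2] > peak_window[1])
    stop_pv("pressvigor_error_input",
            "baseline and peak windows must not overlap (peak after baseline)")
  fs <- trace$fs; n <- length(trace$v)
  vapply(event_times, function(tt) {
    ib <- round((tt + baseline_window - trace$t0) * fs) + 1
    ip <- round((tt + peak_window - trace$t0) * fs) + 1
    if (ib[1] < 1 || ip[2] > n) return(NA_real_)
    max(trace$v[ip[1]:ip[2]]) - mean(trace$v[ib[1]:ib[2]])
  }, numeric(1))
}
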