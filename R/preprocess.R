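# Preprocessing: zero-phase Butterworth bandpass and epoch cropping.

# Design a Butterworth bandpass for the epoch's sampling rate.
design_bandpass <- function(low_hz, high_hz, order, fs) {
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order)) {
    tfb_stop("filter order must be a positive integer", "tfbcsp_invalid_parameter")
  }
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    tfb_stop(sprintf(
      "band edges must satisfy 0 < low (%g) < high (%g) < fs/2 (%g)",
      low_hz, high_hz, fs / 2), "tfbcsp_invalid_parameter")
  }
  signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
}

# Forward-backward filtering of one channel with odd-reflection edge padding
# of length 3x the polynomial order of the designed filter, suppressing
# startup transients on short (2 s) segments.
zero_phase_filter <- function(b, a, x) {
  nf <- max(length(b), length(a)) - 1L
  pad <- 3L * nf
  n <- length(x)
  if (pad >= n) {
    tfb_stop(sprintf("epoch too short (%d samples) for %d-sample edge padding",
                     n, pad), "tfbcsp_invalid_data")
  }
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filter(b, a, xe)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth bandpass filtering of epoched EEG
#'
#' Filters every channel of every trial independently with a Butterworth
#' bandpass applied forward and backward (zero phase, no group delay; the
#' effective magnitude order is twice the design order). Edges are handled
#' with odd-reflection padding so 2-s windows carry no startup transient.
#'
#' @param epochs an [epoch_set()].
#' @param low_hz,high_hz passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param order design order of the Butterworth prototype (default 5).
#' @return A same-shaped `epoch_set`, labels and metadata preserved.
#' @examples
#' ep <- epoch_set(array(rnorm(2 * 2 * 500), c(2, 2, 500)),
#'                 c("L", "R"), fs = 250)
#' filtered <- bandpass_filter(ep, 4, 40)
#' @export
bandpass_filter <- function(epochs, low_hz, high_hz, order = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!all(is.finite(epochs$data))) {
    tfb_stop("epoch data contain non-finite samples", "tfbcsp_invalid_data")
  }
  filt <- design_bandpass(low_hz, high_hz, order, epochs$fs)
  b <- filt$b; a <- filt$a
  out <- epochs$data
  for (i in seq_len(n_trials(epochs))) {
    for (j in seq_len(n_channels(epochs))) {
      out[i, j, ] <- zero_phase_filter(b, a, epochs$data[i, j, ])
    }
  }
  epoch_set(out, epochs$labels, epochs$fs, epochs$channel_names, epochs$t0)
}

#' Crop epochs to a trial-relative time window
#'
#' Keeps the half-open sample interval corresponding to `[t_start, t_end)` ms
#' relative to trial onset; the returned sample count is
#' `round((t_end - t_start)/1000 * fs)` and `t0` is updated. Half-open
#' windows avoid double-counting boundary samples across overlapping windows.
#'
#' @param epochs an [epoch_set()].
#' @param t_start,t_end window bounds in ms, trial-relative; must lie inside
#'   the epoch extent with `t_start < t_end`.
#' @return The cropped `epoch_set`.
#' @examples
#' ep <- epoch_set(array(rnorm(1 * 1 * 1750), c(1, 1, 1750)), "L", fs = 250)
#' cropped <- crop_window(ep, 500, 4500)  # 1000 samples
#' @export
crop_window <- function(epochs, t_start, t_end) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!(t_start < t_end)) {
    tfb_stop("t_start must be strictly less than t_end", "tfbcsp_out_of_range")
  }
  if (t_start < epochs$t0 - 1e-9 || t_end > epoch_end_ms(epochs) + 1e-9) {
    tfb_stop(sprintf("window [%g, %g) ms outside epoch extent [%g, %g) ms",
                     t_start, t_end, epochs$t0, epoch_end_ms(epochs)),
             "tfbcsp_out_of_range")
  }
  fs <- epochs$fs
  s0 <- round((t_start - epochs$t0) * fs / 1000)
  n_out <- round((t_end - t_start) * fs / 1000)
  if (n_out < 1) tfb_stop("window spans no samples", "tfbcsp_out_of_range")
  if (s0 + n_out > n_samples(epochs)) {
    tfb_stop("window exceeds epoch extent", "tfbcsp_out_of_range")
  }
  out <- epochs$data[, , (s0 + 1):(s0 + n_out), drop = FALSE]
  epoch_set(out, epochs$labels, fs, epochs$channel_names,
            epochs$t0 + s0 / fs * 1000)
}
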