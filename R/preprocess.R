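#' Zero-phase band-pass filtering
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase, no group delay) to every channel of every trial
#' independently. Motor-imagery work typically keeps the mu (8-13 Hz) and
#' beta (14-32 Hz) rhythms, i.e. `bandpass(ep, 8, 32)`.
#'
#' @param epochs an [epoch_set()].
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @return An `epoch_set` of identical shape.
#' @export
bandpass <- function(epochs, low_hz, high_hz) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop_param(sprintf(
      "band [%g, %g] Hz must satisfy 0 < low < high < fs/2 = %g",
      low_hz, high_hz, fs / 2
    ))
  }
  # ~3 time constants of the 4th-order band-pass edge response
  if (n_samples(epochs) < 3 * fs / low_hz) {
    warn("trials are short relative to the filter settling time; edge samples may be distorted")
  }
  bf <- signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- epochs$data
  for (t in seq_len(n_trials(epochs))) {
    for (c in seq_len(n_channels(epochs))) {
      out[t, c, ] <- signal::filtfilt(bf, epochs$data[t, c, ])
    }
  }
  epoch_set(out, epochs$labels, fs, epochs$channel_names)
}

#' Extract a sample interval from every trial
#'
#' Slices the same 1-based inclusive interval `[start, end]` out of each
#' trial, e.g. the task-execution window of an imagery paradigm (a 128-Hz
#' recording cued at 3 s is often cut to samples 451..900).
#'
#' @param epochs an [epoch_set()].
#' @param start,end 1-based inclusive sample indices, `1 <= start <= end <=
#'   n_samples`.
#' @return An `epoch_set` with `end - start + 1` samples per trial.
#' @export
segment_epochs <- function(epochs, start, end) {
  stopifnot(inherits(epochs, "epoch_set"))
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < start) {
    stop_param(sprintf("need 1 <= start <= end; got [%d, %d]", start, end))
  }
  if (end > n_samples(epochs)) {
    stop_param(sprintf("end = %d exceeds trial length %d", end, n_samples(epochs)))
  }
  epoch_set(epochs$data[, , start:end, drop = FALSE], epochs$labels,
            epochs$fs, epochs$channel_names)
}
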