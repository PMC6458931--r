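#' Epoched multichannel signal set
#'
#' `epoch_set()` bundles a trials x channels x samples array with per-trial
#' class labels, the sampling rate and channel names. It is the universal
#' input of the package: preprocessing, channel selection, entropy feature
#' extraction and the synthetic generator all consume and produce it.
#'
#' @param data numeric array of shape (n_trials, n_channels, n_samples); all
#'   values must be finite.
#' @param labels integer vector of per-trial class labels, one per trial;
#'   only classes 1 and 2 are meaningful (a filtered subset may contain one).
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector of channel identifiers; defaults to
#'   `"ch1"`, `"ch2"`, ...
#'
#' @return An object of class `epoch_set`: a list with elements `data`,
#'   `labels`, `fs` and `channel_names`.
#' @examples
#' x <- array(rnorm(2 * 3 * 16), dim = c(2, 3, 16))
#' ep <- epoch_set(x, labels = c(1, 2), fs = 128)
#' ep
#' @export
epoch_set <- function(data, labels, fs, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_format("`data` must be a 3-d array (trials x channels x samples)")
  }
  storage.mode(data) <- "double"
  d <- dim(data)
  if (d[1] < 1L || d[2] < 1L || d[3] < 1L) {
    stop_format(sprintf(
      "epoch array needs >= 1 trial, >= 1 channel, >= 1 sample; got %d x %d x %d",
      d[1], d[2], d[3]
    ))
  }
  if (!all(is.finite(data))) stop_format("epoch data contains non-finite values")
  labels <- as.integer(labels)
  if (length(labels) != d[1]) {
    stop_format(sprintf(
      "labels length (%d) must equal the number of trials (%d)",
      length(labels), d[1]
    ))
  }
  if (!all(labels %in% c(1L, 2L))) {
    stop_format("labels must take values in {1, 2}")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_param("`fs` must be a positive scalar sampling rate in Hz")
  }
  channel_names <- channel_names %||% paste0("ch", seq_len(d[2]))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != d[2]) {
    stop_format("channel_names length must equal the number of channels")
  }
  structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = channel_names),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$fs
  ))
  tab <- table(factor(x$labels, levels = c(1, 2)))
  cat(sprintf("  labels: class 1 = %d, class 2 = %d\n", tab[[1]], tab[[2]]))
  cat("  channels: ", paste(x$channel_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]
n_channels <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

#' Extract one trial as a channels x samples matrix
#'
#' @param epochs an [epoch_set()].
#' @param trial trial index (1-based).
#' @return Numeric matrix with one row per channel.
#' @export
trial_matrix <- function(epochs, trial) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (trial < 1L || trial > n_trials(epochs)) {
    stop_param(sprintf("trial index %d out of range 1..%d", trial, n_trials(epochs)))
  }
  m <- matrix(epochs$data[trial, , ], nrow = n_channels(epochs))
  rownames(m) <- epochs$channel_names
  m
}

#' Keep a subset of channels
#'
#' @param epochs an [epoch_set()].
#' @param channels integer indices or channel names, kept in the given order.
#' @return An `epoch_set` restricted (and reordered) to `channels`.
#' @export
subset_channels <- function(epochs, channels) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(channels)) {
    idx <- match(channels, epochs$channel_names)
    if (anyNA(idx)) {
      stop_param(paste0("unknown channel(s): ",
                        paste(channels[is.na(idx)], collapse = ", ")))
    }
  } else {
    idx <- as.integer(channels)
    if (any(idx < 1L) || any(idx > n_channels(epochs))) {
      stop_param("channel index out of range")
    }
  }
  epoch_set(epochs$data[, idx, , drop = FALSE], epochs$labels, epochs$fs,
            epochs$channel_names[idx])
}

#' Tidy view of an epoch set
#'
#' Long-format tibble with one row per (trial, channel, sample).
#'
#' @param x an [epoch_set()].
#' @param ... unused.
#' @return A tibble with columns `trial`, `label`, `channel`, `time`
#'   (seconds, first sample at 0) and `value`.
#' @export
as_tibble.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    label = rep(x$labels, times = d[2] * d[3]),
    channel = rep(rep(x$channel_names, each = d[1]), times = d[3]),
    time = rep((seq_len(d[3]) - 1) / x$fs, each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}
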