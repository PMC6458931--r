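#' Welch power spectral density
#'
#' Averaged modified periodogram: the series is cut into Hann-windowed
#' segments of `seg_len` samples with 50% overlap, each segment is mean-
#' detrended, and the one-sided periodograms are averaged. Density scaling,
#' so `sum(psd) * fs / seg_len` approximates the series variance.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples; default `min(length(x), fs)`.
#' @return A tibble with columns `freq` (Hz) and `psd` (power / Hz).
#' @export
welch_psd <- function(x, fs, seg_len = NULL) {
  n <- length(x)
  if (n < 8L) stop_param("series too short for a PSD estimate (need >= 8 samples)")
  L <- as.integer(seg_len %||% min(n, floor(fs)))
  L <- max(8L, min(n, L))
  step <- max(1L, floor(L / 2))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  U <- sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    acc <- acc + Mod(X)^2 / (fs * U)
  }
  psd <- acc / length(starts)
  # fold negative frequencies into the positive bins (not DC; not Nyquist when L even)
  dbl <- if (L %% 2L == 0L) seq(2L, nf - 1L) else seq(2L, nf)
  psd[dbl] <- 2 * psd[dbl]
  tibble(freq = (seq_len(nf) - 1) * fs / L, psd = psd)
}

#' Mean band power of a single series
#'
#' Mean of the Welch PSD over the frequency bins inside `[band[1], band[2]]`
#' (inclusive).
#'
#' @param x numeric vector (one channel of one trial).
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, band edges in Hz within `(0, fs/2)`.
#' @return Non-negative scalar.
#' @export
band_power <- function(x, fs, band) {
  if (length(band) != 2L || band[1] >= band[2] || band[1] <= 0 || band[2] >= fs / 2) {
    stop_param("`band` must be c(low, high) with 0 < low < high < fs/2")
  }
  spec <- welch_psd(x, fs)
  inb <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(inb)) {
    stop_param(sprintf("no PSD bins fall inside [%g, %g] Hz", band[1], band[2]))
  }
  mean(spec$psd[inb])
}

#' Fisher scores of per-channel band power
#'
#' For each channel the band power of every trial is computed, and the
#' channel is scored by
#' \deqn{F(i) = \frac{(P_1(i) - P_2(i))^2}{\mathrm{var}(P_1(i)) + \mathrm{var}(P_2(i))}}
#' where \eqn{P_c(i)} is the class-mean band power on channel \eqn{i} and the
#' variances are unbiased (n-1) across-trial variances of per-trial band
#' power. Large scores mark channels whose band power discriminates the two
#' classes; a channel with zero variance in both classes gets `NaN`.
#'
#' @param epochs an [epoch_set()] containing both classes with >= 2 trials each.
#' @param band length-2 numeric band in Hz (commonly the preprocessing band,
#'   e.g. `c(8, 32)`).
#' @return A tibble with one row per channel: `channel`, `channel_name`,
#'   `fisher_score`, `power_class1`, `power_class2`, `var_class1`,
#'   `var_class2`, ordered by channel index.
#' @export
fisher_scores <- function(epochs, band = c(8, 32)) {
  stopifnot(inherits(epochs, "epoch_set"))
  for (cls in 1:2) {
    if (sum(epochs$labels == cls) < 2L) {
      stop_data(sprintf(
        "class %d has %d trial(s); need >= 2 per class for across-trial variance",
        cls, sum(epochs$labels == cls)
      ))
    }
  }
  p <- n_channels(epochs)
  pw <- matrix(0, n_trials(epochs), p)
  for (t in seq_len(n_trials(epochs))) {
    for (c in seq_len(p)) {
      pw[t, c] <- band_power(epochs$data[t, c, ], epochs$fs, band)
    }
  }
  i1 <- epochs$labels == 1L
  m1 <- colMeans(pw[i1, , drop = FALSE]); m2 <- colMeans(pw[!i1, , drop = FALSE])
  v1 <- apply(pw[i1, , drop = FALSE], 2L, var)
  v2 <- apply(pw[!i1, , drop = FALSE], 2L, var)
  score <- ifelse(v1 + v2 > 0, (m1 - m2)^2 / (v1 + v2), NaN)
  tibble(
    channel = seq_len(p), channel_name = epochs$channel_names,
    fisher_score = score, power_class1 = m1, power_class2 = m2,
    var_class1 = v1, var_class2 = v2
  )
}

#' Select the top-scoring channels
#'
#' @param scores tibble from [fisher_scores()] (needs columns `channel` and
#'   `fisher_score`).
#' @param k number of channels to keep, `1 <= k <= nrow(scores)`.
#' @return Integer vector of `k` channel indices in descending score order;
#'   ties broken by lower channel index. `NaN` scores rank last.
#' @export
select_channels <- function(scores, k) {
  if (!all(c("channel", "fisher_score") %in% names(scores))) {
    stop_param("`scores` must have columns `channel` and `fisher_score`")
  }
  k <- as.integer(k)
  if (k < 1L || k > nrow(scores)) {
    stop_param(sprintf("k must be in 1..%d; got %d", nrow(scores), k))
  }
  key <- ifelse(is.nan(scores$fisher_score), -Inf, scores$fisher_score)
  ord <- order(-key, scores$channel)
  as.integer(scores$channel[ord][seq_len(k)])
}

#' Bar chart of channel Fisher scores
#'
#' @param scores tibble from [fisher_scores()].
#' @param k optional; highlight the top-`k` channels.
#' @return A ggplot object.
#' @export
plot_fisher_scores <- function(scores, k = NULL) {
  scores <- dplyr::mutate(scores, selected = FALSE)
  if (!is.null(k)) scores$selected[scores$channel %in% select_channels(scores, k)] <- TRUE
  ggplot2::ggplot(scores, ggplot2::aes(
    x = stats::reorder(.data$channel_name, .data$channel),
    y = .data$fisher_score, fill = .data$selected
  )) +
    ggplot2::geom_col(show.legend = !is.null(k)) +
    ggplot2::labs(x = "channel", y = "Fisher score", fill = "selected") +
    ggplot2::theme_minimal()
}
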