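#' Entropy estimator configuration
#'
#' Collects every tunable of the multivariate multiscale fuzzy entropy
#' estimators. The defaults (`m = 2`, `lam = 1`, threshold `r` of 0.2 in units of the
#' standardized signal's SD) are the conventional choices for short
#' biomedical epochs.
#'
#' @param m embedding dimension per channel; scalar (recycled) or one value
#'   per channel, all `>= 1`.
#' @param lam time delay per channel; scalar or per channel, all `>= 1`.
#' @param r similarity threshold of the fuzzy membership function
#'   `exp(-d^2 / r)`; with `normalize = TRUE` it is expressed in units of the
#'   per-channel SD (each channel is standardized first), otherwise it is
#'   multiplied by the pooled SD of the trial.
#' @param scale_max largest coarse-graining scale factor `tau`.
#' @param median_window sliding median window length in samples (used by the
#'   `"IRCmvMFE"` variant; `1` disables the filter). A window of 3 is the
#'   smallest that rejects isolated impulses.
#' @param variant `"IRCmvMFE"` (median filter, all coarse-grain offsets),
#'   `"RCmvMFE"` (no median filter, all offsets) or `"mvMFE"` (no median
#'   filter, offset 1 only).
#' @param normalize standardize each channel (zero mean, unit SD over the
#'   analyzed segment, measured after the median filter so impulses cannot
#'   inflate the scale), so one scalar `r` applies to all channels.
#' @return An object of class `entropy_config`.
#' @export
entropy_config <- function(m = 2, lam = 1, r = 0.2, scale_max = 20,
                           median_window = 3,
                           variant = c("IRCmvMFE", "RCmvMFE", "mvMFE"),
                           normalize = TRUE) {
  variant <- match.arg(variant)
  m <- as.integer(m); lam <- as.integer(lam)
  if (any(m < 1L)) stop_param("all embedding dimensions `m` must be >= 1")
  if (any(lam < 1L)) stop_param("all time delays `lam` must be >= 1")
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop_param("`r` must be a positive scalar")
  scale_max <- as.integer(scale_max)
  if (scale_max < 1L) stop_param("`scale_max` must be >= 1")
  median_window <- as.integer(median_window)
  if (median_window < 1L) stop_param("`median_window` must be >= 1")
  structure(
    list(m = m, lam = lam, r = r, scale_max = scale_max,
         median_window = median_window, variant = variant,
         normalize = isTRUE(normalize)),
    class = "entropy_config"
  )
}

#' @export
print.entropy_config <- function(x, ...) {
  cat(sprintf(
    "<entropy_config> %s: m = %s, lam = %s, r = %g, scale_max = %d, median_window = %d, normalize = %s\n",
    x$variant, paste(x$m, collapse = "/"), paste(x$lam, collapse = "/"),
    x$r, x$scale_max, x$median_window, x$normalize
  ))
  invisible(x)
}
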