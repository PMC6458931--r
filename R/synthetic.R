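#' Specification of a synthetic two-class oscillatory epoch set
#'
#' Describes a simple generative model of few-channel motor-imagery-like
#' EEG: per-trial mu-band (8-13 Hz) and beta-band (14-32 Hz) sinusoids with
#' class-dependent amplitudes and random phases, first-order autoregressive
#' colored background noise, additive white Gaussian noise, and an optional
#' sparse train of high-amplitude impulses (eye-blink / motion-like bursts).
#'
#' The default amplitudes give one class a strong sensorimotor rhythm and
#' the other an attenuated one (event-related desynchronization), so the
#' classes differ in band power and in signal complexity.
#'
#' @param n_trials_per_class trials per class.
#' @param n_channels,n_samples,fs geometry: channels, samples per trial,
#'   sampling rate (Hz). Defaults mimic a 3-channel 128-Hz recording cut to
#'   a 450-sample imagery window.
#' @param class_band_amps list of two lists (classes 1 and 2), each with
#'   numeric vectors `mu` and `beta` of per-channel oscillator amplitudes
#'   (recycled across channels).
#' @param ar_noise_coeff AR(1) coefficient of the colored noise, in `[0, 1)`.
#' @param ar_noise_sd innovation SD of the AR(1) noise.
#' @param gauss_sd SD of the additive white Gaussian noise.
#' @param impulse_prob per-sample Bernoulli probability of an impulse, in
#'   `[0, 0.05]`.
#' @param impulse_amp impulse magnitude in units of the clean signal's SD.
#' @param seed integer seed; identical spec + seed gives bit-identical data.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_trials_per_class = 60, n_channels = 3,
                       n_samples = 450, fs = 128,
                       class_band_amps = list(
                         list(mu = 1.2, beta = 0.8),
                         list(mu = 0.45, beta = 0.3)
                       ),
                       ar_noise_coeff = 0.9, ar_noise_sd = 0.2,
                       gauss_sd = 0.5, impulse_prob = 0, impulse_amp = 0,
                       seed = 1) {
  if (impulse_prob < 0 || impulse_prob > 0.05) {
    stop_param("`impulse_prob` must lie in [0, 0.05]")
  }
  if (impulse_amp < 0) stop_param("`impulse_amp` must be >= 0")
  if (ar_noise_coeff < 0 || ar_noise_coeff >= 1) {
    stop_param("`ar_noise_coeff` must lie in [0, 1)")
  }
  if (length(class_band_amps) != 2L ||
      !all(vapply(class_band_amps, function(a) {
        all(c("mu", "beta") %in% names(a))
      }, logical(1)))) {
    stop_param("`class_band_amps` must list `mu` and `beta` amplitudes for both classes")
  }
  structure(
    list(n_trials_per_class = as.integer(n_trials_per_class),
         n_channels = as.integer(n_channels),
         n_samples = as.integer(n_samples), fs = as.numeric(fs),
         class_band_amps = class_band_amps,
         ar_noise_coeff = ar_noise_coeff, ar_noise_sd = ar_noise_sd,
         gauss_sd = gauss_sd, impulse_prob = impulse_prob,
         impulse_amp = impulse_amp, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Generate a synthetic two-class epoch set
#'
#' Labels alternate 1, 2, 1, 2, ... Every random draw (oscillator
#' frequencies and phases, noise, impulse positions and signs) comes from a
#' RNG stream seeded by `spec$seed`, so the output is reproducible
#' bit-for-bit.
#'
#' @param spec a [synth_spec()].
#' @return An [epoch_set()] with `2 * n_trials_per_class` trials.
#' @examples
#' ep <- generate_epochs(synth_spec(n_trials_per_class = 5, seed = 42))
#' dim(ep)
#' @export
generate_epochs <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  nt <- 2L * spec$n_trials_per_class
  p <- spec$n_channels; ns <- spec$n_samples
  labels <- rep_len(c(1L, 2L), nt)
  tt <- (seq_len(ns) - 1) / spec$fs
  arr <- withr::with_seed(spec$seed, {
    a <- array(0, dim = c(nt, p, ns))
    for (t in seq_len(nt)) {
      amps <- spec$class_band_amps[[labels[t]]]
      amp_mu <- rep_len(amps$mu, p); amp_beta <- rep_len(amps$beta, p)
      f_mu <- stats::runif(1, 8, 13)
      f_beta <- stats::runif(1, 14, 32)
      for (c in seq_len(p)) {
        x <- amp_mu[c] * sin(2 * pi * f_mu * tt + stats::runif(1, 0, 2 * pi)) +
          amp_beta[c] * sin(2 * pi * f_beta * tt + stats::runif(1, 0, 2 * pi))
        if (spec$ar_noise_sd > 0) {
          x <- x + as.numeric(stats::filter(
            stats::rnorm(ns, 0, spec$ar_noise_sd),
            spec$ar_noise_coeff, method = "recursive"
          ))
        }
        if (spec$gauss_sd > 0) x <- x + stats::rnorm(ns, 0, spec$gauss_sd)
        if (spec$impulse_prob > 0 && spec$impulse_amp > 0) {
          hit <- stats::runif(ns) < spec$impulse_prob
          if (any(hit)) {
            x[hit] <- x[hit] + sample(c(-1, 1), sum(hit), replace = TRUE) *
              spec$impulse_amp * sd(x)
          }
        }
        a[t, c, ] <- x
      }
    }
    a
  })
  nm <- if (p == 3L) c("C3", "Cz", "C4") else paste0("ch", seq_len(p))
  epoch_set(arr, labels, spec$fs, nm)
}

#' Add sparse impulse noise to an epoch set
#'
#' Seeded contamination used for robustness studies: at each
#' Bernoulli-selected sample an impulse of `+/- impulse_amp` times that
#' channel-trial's SD is added. The input object is not modified.
#'
#' @param epochs an [epoch_set()].
#' @param impulse_prob per-sample impulse probability.
#' @param impulse_amp impulse magnitude in SD units.
#' @param seed integer seed.
#' @return A contaminated copy of `epochs`.
#' @export
contaminate <- function(epochs, impulse_prob, impulse_amp, seed = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (impulse_prob < 0 || impulse_prob > 1) stop_param("`impulse_prob` must lie in [0, 1]")
  if (impulse_prob == 0 || impulse_amp == 0) return(epochs)
  d <- dim(epochs$data)
  out <- withr::with_seed(as.integer(seed), {
    a <- epochs$data
    for (t in seq_len(d[1])) {
      for (c in seq_len(d[2])) {
        hit <- stats::runif(d[3]) < impulse_prob
        if (any(hit)) {
          s <- sd(epochs$data[t, c, ])
          a[t, c, hit] <- a[t, c, hit] +
            sample(c(-1, 1), sum(hit), replace = TRUE) * impulse_amp * s
        }
      }
    }
    a
  })
  epoch_set(out, epochs$labels, epochs$fs, epochs$channel_names)
}
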