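# deterministic small fixtures, built in code

# epoch set with fully reproducible Gaussian content
tiny_epochs <- function(n_trials = 4, n_channels = 3, n_samples = 32,
                        fs = 64, seed = 1) {
  withr::with_seed(seed, {
    arr <- array(rnorm(n_trials * n_channels * n_samples),
                 dim = c(n_trials, n_channels, n_samples))
    epoch_set(arr, rep_len(c(1L, 2L), n_trials), fs)
  })
}

# single-trial sinusoid epoch set (per-channel frequency f, amplitude a)
sine_epochs <- function(freqs, amps = 1, n_samples = 512, fs = 128,
                        labels = NULL, n_trials = 1) {
  p <- length(freqs)
  amps <- rep_len(amps, p)
  tt <- (seq_len(n_samples) - 1) / fs
  arr <- array(0, dim = c(n_trials, p, n_samples))
  for (t in seq_len(n_trials)) {
    for (c in seq_len(p)) arr[t, c, ] <- amps[c] * sin(2 * pi * freqs[c] * tt)
  }
  epoch_set(arr, labels %||% rep_len(c(1L, 2L), n_trials), fs)
}

expect_profiles_equal <- function(a, b, tol = 1e-10) {
  expect_equal(a$scale, b$scale)
  expect_equal(a$valid, b$valid)
  expect_equal(a$entropy, b$entropy, tolerance = tol)
}

`%||%` <- rlang::`%||%`
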