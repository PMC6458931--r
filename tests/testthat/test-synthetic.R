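test_that("generator honours geometry, labels and seeding", {
  spec <- synth_spec(n_trials_per_class = 5, n_channels = 3, n_samples = 450,
                     fs = 128, seed = 7)
  ep <- generate_epochs(spec)
  expect_equal(dim(ep), c(10L, 3L, 450L))
  expect_equal(ep$labels, rep_len(c(1L, 2L), 10))
  expect_equal(ep$channel_names, c("C3", "Cz", "C4"))
  expect_identical(generate_epochs(spec)$data, ep$data)
  expect_false(identical(generate_epochs(synth_spec(n_trials_per_class = 5,
                                                    seed = 8))$data, ep$data))
})

test_that("spec validation bounds the contamination dials", {
  expect_error(synth_spec(impulse_prob = 0.2), class = "mvmfe_param_error")
  expect_error(synth_spec(impulse_amp = -1), class = "mvmfe_param_error")
  expect_error(synth_spec(ar_noise_coeff = 1), class = "mvmfe_param_error")
  expect_error(synth_spec(class_band_amps = list(list(mu = 1))),
               class = "mvmfe_param_error")
})

test_that("clean generation has no impulse-like outliers", {
  # with impulse_prob = 0, samples stay within the Gaussian + oscillator
  # envelope: no |z-score| above 6 in 100 seeded replicates
  n_out <- 0
  for (s in 1:100) {
    ep <- generate_epochs(synth_spec(n_trials_per_class = 1, n_samples = 450,
                                     seed = 9000 + s))
    for (c in 1:3) {
      x <- ep$data[1, c, ]
      n_out <- n_out + sum(abs(x - mean(x)) > 6 * sd(x))
    }
  }
  expect_lte(n_out, 1)
})

test_that("contaminate injects the expected impulse counts, reproducibly", {
  ep <- generate_epochs(synth_spec(n_trials_per_class = 1, n_samples = 450, seed = 1))
  expect_identical(contaminate(ep, 0, 10, seed = 3), ep)
  expect_identical(contaminate(ep, 0.5, 0, seed = 3), ep)

  c1 <- contaminate(ep, 0.01, 10, seed = 3)
  expect_identical(contaminate(ep, 0.01, 10, seed = 3)$data, c1$data)
  expect_false(identical(contaminate(ep, 0.01, 10, seed = 4)$data, c1$data))
  expect_identical(ep$data, generate_epochs(synth_spec(n_trials_per_class = 1,
                                                       n_samples = 450,
                                                       seed = 1))$data)

  # counts across 100 seeds: Binomial(450, 0.01) per channel-trial
  counts <- integer(0)
  for (s in 1:100) {
    cc <- contaminate(ep, 0.01, 10, seed = 100 + s)
    counts <- c(counts, sum(cc$data[1, 1, ] != ep$data[1, 1, ]))
  }
  expect_gt(mean(counts), qpois(0.005, 4.5 * 100) / 100)
  expect_lt(mean(counts), qpois(0.995, 4.5 * 100) / 100)
})

test_that("two classes with identical parameters are not separable by Fisher score", {
  # for each of 8 identically parameterized datasets, the observed max score
  # is compared with the 95th percentile of its own label-permutation null;
  # at most 2 exceedances are compatible with the 5% nominal rate
  exceed <- 0
  for (k in 1:8) {
    spec <- synth_spec(
      n_trials_per_class = 10, n_channels = 3, n_samples = 256,
      class_band_amps = list(list(mu = 1, beta = 0.6), list(mu = 1, beta = 0.6)),
      seed = 310 + k
    )
    ep <- generate_epochs(spec)
    obs <- max(fisher_scores(ep, c(8, 32))$fisher_score)
    null_max <- withr::with_seed(17 + k, replicate(40, {
      perm <- epoch_set(ep$data, sample(ep$labels), ep$fs)
      max(fisher_scores(perm, c(8, 32))$fisher_score)
    }))
    exceed <- exceed + (obs > quantile(null_max, 0.95))
  }
  expect_lte(exceed, 2)
})

test_that("a noise-dominated class has higher small-scale entropy than a rhythmic one", {
  # contrast is measured without the median pre-filter, which would strip
  # exactly the sample-scale irregularity being compared
  cfg <- entropy_config(scale_max = 1, variant = "RCmvMFE")
  ent_of <- function(spec) {
    ep <- generate_epochs(spec)
    mean(vapply(seq_len(dim(ep)[1]),
                function(t) entropy_profile(trial_matrix(ep, t), cfg)$entropy,
                numeric(1)))
  }
  rhythmic <- ent_of(synth_spec(
    n_trials_per_class = 15, n_samples = 450, ar_noise_sd = 0, gauss_sd = 0.1,
    class_band_amps = list(list(mu = 1, beta = 0.6), list(mu = 1, beta = 0.6)),
    seed = 20
  ))
  noisy <- ent_of(synth_spec(
    n_trials_per_class = 15, n_samples = 450, ar_noise_sd = 0, gauss_sd = 1,
    class_band_amps = list(list(mu = 0.01, beta = 0.01), list(mu = 0.01, beta = 0.01)),
    seed = 21
  ))
  expect_gt(noisy, rhythmic + 0.05)
})
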