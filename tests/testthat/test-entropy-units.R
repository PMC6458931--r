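test_that("median_filter handles odd, even and unit windows", {
  expect_equal(median_filter(c(1, 5, 2), 3), c(3, 2, 3.5))
  x <- rnorm(20)
  expect_identical(median_filter(x, 1), x)
  # even window: mean of the two middle order statistics
  expect_equal(median_filter(c(3, 7), 2)[1], 5)
  # isolated impulse is removed
  expect_equal(median_filter(c(0, 0, 100, 0, 0), 3), rep(0, 5))
  expect_error(median_filter(x, 0), class = "mvmfe_param_error")
})

test_that("coarse_grain computes offset block means with exact bounds", {
  expect_equal(coarse_grain(c(1, 3, 5, 7), 2, 1), c(2, 6))
  # offset 2: only the window (3, 5) is complete
  expect_equal(coarse_grain(c(1, 3, 5, 7), 2, 2), 4)
  x <- rnorm(17)
  expect_identical(coarse_grain(x, 1, 1), x)
  expect_length(coarse_grain(x, 5, 1), 3)
  expect_length(coarse_grain(x, 5, 4), 2)
  expect_error(coarse_grain(rnorm(3), 5, 1), class = "mvmfe_data_error")
  expect_error(coarse_grain(x, 2, 3), class = "mvmfe_param_error")
})

test_that("embed_multivariate enumerates composite delay vectors", {
  y <- rbind(c(1, 2, 3, 4), c(10, 20, 30, 40))
  z <- embed_multivariate(y, c(2, 2), c(1, 1))
  expect_equal(z, rbind(c(1, 2, 10, 20), c(2, 3, 20, 30)))

  z1 <- embed_multivariate(y, c(1, 1), c(1, 1))
  expect_equal(nrow(z1), 3) # N' - n with n = 1
  expect_equal(z1[2, ], c(2, 20))

  # univariate reduction: N' - n vectors with n = m * lam = 2
  zu <- embed_multivariate(matrix(1:5, nrow = 1), 2, 1)
  expect_equal(zu, rbind(c(1, 2), c(2, 3), c(3, 4)) * 1.0)
  expect_error(embed_multivariate(y, c(4, 4), c(1, 1)), class = "mvmfe_data_error")
})

test_that("chebyshev_distance and fuzzy_similarity follow their closed forms", {
  expect_equal(chebyshev_distance(c(1, 2, 3), c(1, 5, 3)), 3)
  expect_equal(chebyshev_distance(1:4, 1:4), 0)
  withr::with_seed(8, {
    for (i in 1:20) {
      u <- rnorm(5); v <- rnorm(5)
      expect_equal(chebyshev_distance(u, v), chebyshev_distance(v, u))
      expect_equal(chebyshev_distance(u, v), max(abs(u - v)))
    }
  })
  expect_error(chebyshev_distance(1:3, 1:4), class = "mvmfe_param_error")

  expect_equal(fuzzy_similarity(0, 0.2), 1)
  expect_equal(fuzzy_similarity(sqrt(0.3), 0.3), exp(-1))
  d <- seq(0, 3, by = 0.1)
  expect_true(all(diff(fuzzy_similarity(d, 0.5)) < 0))
  expect_error(fuzzy_similarity(1, 0), class = "mvmfe_param_error")
})

test_that("membership_grade matches a double-loop summation oracle", {
  withr::with_seed(33, {
    for (i in 1:5) {
      z <- matrix(rnorm(6 * 4), nrow = 6)
      r <- runif(1, 0.1, 0.6)
      brute <- mean(sapply(1:6, function(a) {
        mean(sapply(setdiff(1:6, a), function(b) {
          exp(-max(abs(z[a, ] - z[b, ]))^2 / r)
        }))
      }))
      expect_equal(membership_grade(z, r), brute, tolerance = 1e-12)
    }
  })
  # identical vectors -> grade 1; two vectors -> single-pair similarity
  expect_equal(membership_grade(matrix(1, 4, 3), 0.2), 1)
  z2 <- rbind(c(0, 0), c(0.3, 0.1))
  expect_equal(membership_grade(z2, 0.25), exp(-0.09 / 0.25))
  expect_error(membership_grade(matrix(1, 1, 3), 0.2), class = "mvmfe_data_error")
})

test_that("mv_fuzzy_entropy grades match the brute-force pooled-set oracle", {
  cfg <- entropy_config(m = 2, lam = 1, r = 0.25, normalize = FALSE)
  withr::with_seed(12, {
    y <- matrix(rnorm(2 * 8), nrow = 2)
    got <- mv_fuzzy_entropy(y, cfg)
    # independent enumeration: base vectors and per-channel extensions
    v <- 8 - 2
    z <- t(sapply(1:v, function(i) c(y[1, i], y[1, i + 1], y[2, i], y[2, i + 1])))
    grade <- function(zs, base) {
      n <- nrow(zs); tot <- 0; np <- 0
      for (a in 1:n) for (b in 1:n) {
        if (base[a] == base[b]) next
        tot <- tot + exp(-max(abs(zs[a, ] - zs[b, ]))^2 / cfg$r); np <- np + 1
      }
      tot / np
    }
    expect_equal(unname(got["phi_m"]), grade(z, 1:v), tolerance = 1e-12)
    ze <- rbind(cbind(z, y[1, 1:v + 2]), cbind(z, y[2, 1:v + 2]))
    expect_equal(unname(got["phi_m1"]), grade(ze, rep(1:v, 2)), tolerance = 1e-12)
  })

  # constant multichannel signal: all grades 1
  const <- mv_fuzzy_entropy(matrix(5, 2, 10), entropy_config(normalize = FALSE))
  expect_equal(unname(const), c(1, 1))

  # single channel reduces to the univariate fuzzy-entropy machinery
  withr::with_seed(4, x <- rnorm(30))
  uni <- mv_fuzzy_entropy(matrix(x, 1), cfg)
  z <- cbind(x[1:28], x[2:29])
  phi_m <- mean(sapply(1:28, function(a) mean(sapply(setdiff(1:28, a), function(b)
    exp(-max(abs(z[a, ] - z[b, ]))^2 / cfg$r)))))
  expect_equal(unname(uni["phi_m"]), phi_m, tolerance = 1e-12)
})
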