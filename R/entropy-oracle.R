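# Brute-force reference twin of entropy_profile(), written as plain nested
# loops with its own median filter, coarse-graining, embedding and distance
# code. Deliberately shares nothing with the production path so the two can
# check each other; intended for small inputs (N <= 64 or so).

#' Naive reference implementation of the entropy profile
#'
#' Loop-by-loop re-derivation of [entropy_profile()] used as an independent
#' cross-check in the test suite. Identical contract and return shape, but
#' every step (median filter, coarse-graining, embedding, Chebyshev
#' distances, membership sums) is an explicit R loop. Orders of magnitude
#' slower; use only on small inputs.
#'
#' @inheritParams entropy_profile
#' @return Same tibble shape as [entropy_profile()].
#' @export
entropy_profile_naive <- function(x, cfg = entropy_config(), scales = NULL, trial = 1L) {
  if (inherits(x, "epoch_set")) x <- trial_matrix(x, trial)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  stopifnot(inherits(cfg, "entropy_config"))
  scales <- as.integer(scales %||% seq_len(cfg$scale_max))
  p <- nrow(x)
  m <- rep_len(cfg$m, p); lam <- rep_len(cfg$lam, p)

  if (cfg$variant == "IRCmvMFE" && cfg$median_window > 1L) {
    w <- cfg$median_window
    lo <- (w - 1L) %/% 2L; hi <- w %/% 2L
    xf <- x
    for (c in seq_len(p)) {
      for (s in seq_len(ncol(x))) {
        win <- sort(x[c, max(1L, s - lo):min(ncol(x), s + hi)])
        nw <- length(win)
        xf[c, s] <- if (nw %% 2L == 1L) win[(nw + 1L) / 2L] else
          (win[nw / 2L] + win[nw / 2L + 1L]) / 2
      }
    }
    x <- xf
  }

  if (cfg$normalize) {
    for (c in seq_len(p)) {
      mu <- sum(x[c, ]) / ncol(x)
      s <- sqrt(sum((x[c, ] - mu)^2) / (ncol(x) - 1))
      if (s == 0) s <- 1
      x[c, ] <- (x[c, ] - mu) / s
    }
    r <- cfg$r
  } else {
    r <- cfg$r * sd(as.vector(x))
    if (r == 0) r <- cfg$r
  }

  n <- max(m) * max(lam)
  rows <- list()
  for (tau in scales) {
    offsets <- if (cfg$variant == "mvMFE") 1L else seq_len(tau)
    ph_m <- numeric(0); ph_m1 <- numeric(0)
    ok <- TRUE
    for (k in offsets) {
      np <- (ncol(x) - k + 1L) %/% tau
      if (np - n < 2L) { ok <- FALSE; break }
      y <- matrix(0, p, np)
      for (c in seq_len(p)) {
        for (j in seq_len(np)) {
          y[c, j] <- mean(x[c, ((j - 1L) * tau + k):(j * tau + k - 1L)])
        }
      }
      v <- np - n
      # base vectors, one per start index
      z <- vector("list", v)
      for (i in seq_len(v)) {
        vec <- numeric(0)
        for (c in seq_len(p)) {
          for (q in 0:(m[c] - 1L)) vec <- c(vec, y[c, i + q * lam[c]])
        }
        z[[i]] <- vec
      }
      ph_m <- c(ph_m, naive_grade(z, r))
      zext <- list(); zbase <- integer(0)
      for (c in seq_len(p)) {
        for (i in seq_len(v)) {
          zext[[length(zext) + 1L]] <- c(z[[i]], y[c, i + m[c] * lam[c]])
          zbase <- c(zbase, i) # base time index; same-index pairs are self-pairs
        }
      }
      ph_m1 <- c(ph_m1, naive_grade(zext, r, zbase))
    }
    if (!ok) {
      rows[[length(rows) + 1L]] <- tibble(scale = tau, entropy = NA_real_,
                                          valid = FALSE, phi_m = NA_real_,
                                          phi_m1 = NA_real_)
      next
    }
    pm <- mean(ph_m); pm1 <- mean(ph_m1)
    valid <- pm > 0 && pm1 > 0
    rows[[length(rows) + 1L]] <- tibble(
      scale = tau, entropy = if (valid) -log(pm1 / pm) else NA_real_,
      valid = valid, phi_m = pm, phi_m1 = pm1
    )
  }
  dplyr::bind_rows(rows)
}

naive_grade <- function(z, r, base_idx = seq_along(z)) {
  v <- length(z)
  total <- 0
  n_pairs <- 0
  for (i in seq_len(v)) {
    for (j in seq_len(v)) {
      if (base_idx[j] == base_idx[i]) next # self (or same base time index)
      d <- 0
      for (l in seq_along(z[[i]])) {
        a <- abs(z[[i]][l] - z[[j]][l])
        if (a > d) d <- a
      }
      total <- total + exp(-d^2 / r)
      n_pairs <- n_pairs + 1
    }
  }
  total / n_pairs
}
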