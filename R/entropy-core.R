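#' Sliding median filter
#'
#' Rank filter that replaces each sample by the median of the window centered
#' on it; isolated high-amplitude impulses are removed where a mean filter
#' would only smear them. For an even window the output is the mean of the
#' two middle order statistics. At the series edges the window is truncated
#' to the available samples (no padding). A window of length `w` at position
#' `s` covers indices `s - floor((w-1)/2) .. s + floor(w/2)`.
#'
#' @param x numeric vector.
#' @param window window length in samples, `>= 1`; `1` is the identity.
#' @return Numeric vector of the same length as `x`.
#' @export
median_filter <- function(x, window) {
  window <- as.integer(window)
  if (window < 1L) stop_param("`window` must be >= 1")
  if (window == 1L) return(x)
  n <- length(x)
  lo <- (window - 1L) %/% 2L
  hi <- window %/% 2L
  vapply(seq_len(n), function(s) {
    median(x[max(1L, s - lo):min(n, s + hi)])
  }, numeric(1))
}

#' Coarse-grain a series at scale tau with an offset
#'
#' Element `j` of the output is the mean of the `tau` consecutive samples
#' starting at position `(j-1) * tau + k_offset`; the output has
#' `floor((N - k_offset + 1) / tau)` elements, so only complete windows are
#' used. Offset `k_offset = 1` is classical coarse-graining; the composite
#' estimators average membership grades over all offsets `1..tau`.
#'
#' @param x numeric vector of length `N`.
#' @param tau scale factor, `>= 1`.
#' @param k_offset phase offset in `1..tau`.
#' @return Numeric vector of block means.
#' @export
coarse_grain <- function(x, tau, k_offset = 1L) {
  tau <- as.integer(tau); k_offset <- as.integer(k_offset)
  if (tau < 1L) stop_param("`tau` must be >= 1")
  if (k_offset < 1L || k_offset > tau) stop_param("`k_offset` must be in 1..tau")
  n_out <- (length(x) - k_offset + 1L) %/% tau
  if (n_out < 1L) {
    stop_data(sprintf(
      "series of length %d too short for one full window at tau = %d, offset %d",
      length(x), tau, k_offset
    ))
  }
  if (tau == 1L) return(x)
  idx <- k_offset + seq_len(n_out * tau) - 1L
  colMeans(matrix(x[idx], nrow = tau))
}

#' Multivariate delay-vector embedding
#'
#' Builds the composite delay vectors of a multichannel series: vector `i`
#' concatenates, channel by channel, the samples
#' `y_c(i), y_c(i + lam_c), ..., y_c(i + (m_c - 1) lam_c)`. With
#' `n = max(m) * max(lam)` there are `N' - n` vectors of total dimension
#' `sum(m)`.
#'
#' @param y numeric matrix, channels x samples (length `N'`).
#' @param m integer vector of per-channel embedding dimensions (recycled).
#' @param lam integer vector of per-channel delays (recycled).
#' @return Numeric matrix with one delay vector per row.
#' @export
embed_multivariate <- function(y, m, lam) {
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  p <- nrow(y); np <- ncol(y)
  m <- rep_len(as.integer(m), p); lam <- rep_len(as.integer(lam), p)
  n <- max(m) * max(lam)
  v <- np - n
  if (v < 1L) {
    stop_data(sprintf("series length %d too short for embedding (need > %d)", np, n))
  }
  cols <- vector("list", sum(m))
  idx <- 1L
  for (c in seq_len(p)) {
    for (q in seq_len(m[c]) - 1L) {
      cols[[idx]] <- y[c, seq_len(v) + q * lam[c]]
      idx <- idx + 1L
    }
  }
  do.call(cbind, cols)
}

#' Chebyshev distance between two vectors
#'
#' @param u,v numeric vectors of equal length.
#' @return `max(abs(u - v))`.
#' @export
chebyshev_distance <- function(u, v) {
  if (length(u) != length(v)) stop_param("vectors must have equal dimension")
  max(abs(u - v))
}

#' Fuzzy similarity of a distance
#'
#' The Gaussian-like membership function `exp(-d^2 / r)`: 1 at distance 0,
#' strictly decreasing in `d`.
#'
#' @param d non-negative distance(s).
#' @param r positive similarity threshold.
#' @return Value(s) in `(0, 1]`.
#' @export
fuzzy_similarity <- function(d, r) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop_param("`r` must be a positive scalar")
  exp(-d^2 / r)
}

#' Average fuzzy membership grade of a delay-vector set
#'
#' `phi = (1/V) sum_i (1/(V-1)) sum_{j != i} exp(-d_ij^2 / r)` with `d_ij`
#' the Chebyshev distance between vectors `i` and `j`; self-pairs excluded.
#'
#' @param vectors numeric matrix, one delay vector per row (`V >= 2`).
#' @param r positive similarity threshold.
#' @return Scalar in `(0, 1]`.
#' @export
membership_grade <- function(vectors, r) {
  if (!is.matrix(vectors)) vectors <- matrix(vectors, ncol = 1L)
  if (nrow(vectors) < 2L) stop_data("need >= 2 delay vectors for a membership grade")
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop_param("`r` must be a positive scalar")
  cpp_membership_grade(vectors, r)
}

# delay vectors extended from dimension m to m+1: for each channel c the base
# vector gains one extra sample y_c(i + m_c * lam_c); the p * V extended
# vectors are pooled into one set.
extend_vectors <- function(y, base, m, lam) {
  p <- nrow(y)
  v <- nrow(base)
  out <- vector("list", p)
  for (c in seq_len(p)) {
    out[[c]] <- cbind(base, y[c, seq_len(v) + m[c] * lam[c]])
  }
  do.call(rbind, out)
}

#' Fuzzy membership grades of a multichannel series at dimensions m and m+1
#'
#' Computes the average membership grade of the composite delay vectors at
#' the configured embedding dimension (`phi_m`) and of the pooled
#' one-sample-extended vectors (`phi_m1`): for each channel the base vectors
#' gain one extra sample of that channel, and the grades are taken over the
#' pooled set of `p * V` extended vectors. Extended pairs that share the
#' same base time index are self-pairs (their base distance is zero) and
#' are excluded from the pooled grade; with that convention every counted
#' extended pair dominates its base pair's distance, so
#' `phi_m1 <= phi_m` and the entropy `-log(phi_m1 / phi_m)` is
#' non-negative.
#'
#' @param y numeric matrix, channels x samples (already coarse-grained /
#'   filtered as desired).
#' @param cfg an [entropy_config()]; only `m`, `lam`, `r` are used.
#' @return Named numeric vector `c(phi_m = ..., phi_m1 = ...)`.
#' @export
mv_fuzzy_entropy <- function(y, cfg = entropy_config()) {
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  p <- nrow(y)
  m <- rep_len(cfg$m, p); lam <- rep_len(cfg$lam, p)
  base <- embed_multivariate(y, m, lam)
  if (nrow(base) < 2L) stop_data("too few delay vectors (need >= 2)")
  phi_m <- membership_grade(base, cfg$r)
  ext <- extend_vectors(y, base, m, lam)
  phi_m1 <- cpp_membership_grade_grouped(ext, cfg$r, nrow(base))
  c(phi_m = phi_m, phi_m1 = phi_m1)
}

#' Multiscale fuzzy entropy profile of one multichannel trial
#'
#' Each channel is median-filtered once (for the `"IRCmvMFE"` variant) and
#' then standardized (when `cfg$normalize`). For each scale `tau` the
#' channel series are coarse-grained at every phase offset
#' `k = 1..tau` (only `k = 1` for `"mvMFE"`), the fuzzy membership grades at
#' dimensions `m` and `m+1` are computed per offset, the grades (not the
#' entropies) are averaged across offsets, and the scale's entropy is
#' `-log(phibar_m1 / phibar_m)`. A scale is invalid (`NA` value) when any
#' offset yields fewer than 2 delay vectors or a grade underflows to zero.
#'
#' @param x numeric matrix, channels x samples (one trial), or an
#'   [epoch_set()] together with `trial`.
#' @param cfg an [entropy_config()].
#' @param scales integer scales to evaluate; default `1:cfg$scale_max`.
#' @param trial trial index when `x` is an `epoch_set`.
#' @return A tibble with columns `scale`, `entropy`, `valid`, `phi_m`,
#'   `phi_m1`. Entropies are non-negative wherever valid.
#' @examples
#' x <- matrix(rnorm(3 * 120), nrow = 3)
#' entropy_profile(x, entropy_config(scale_max = 5))
#' @export
entropy_profile <- function(x, cfg = entropy_config(), scales = NULL, trial = 1L) {
  if (inherits(x, "epoch_set")) x <- trial_matrix(x, trial)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  stopifnot(inherits(cfg, "entropy_config"))
  scales <- as.integer(scales %||% seq_len(cfg$scale_max))
  if (any(scales < 1L)) stop_param("scales must be >= 1")
  p <- nrow(x)
  m <- rep_len(cfg$m, p); lam <- rep_len(cfg$lam, p)

  # median filter precedes standardization: an impulse inflates the raw SD,
  # and scaling by it would perturb the whole profile even after the filter
  # removes the impulse itself
  use_median <- cfg$variant == "IRCmvMFE" && cfg$median_window > 1L
  if (use_median) {
    x <- t(apply(x, 1L, median_filter, window = cfg$median_window))
  }
  if (cfg$normalize) {
    sds <- apply(x, 1L, sd)
    if (any(sds == 0)) sds[sds == 0] <- 1 # constant channel: leave centered at 0
    x <- (x - rowMeans(x)) / sds
    r <- cfg$r
  } else {
    r <- cfg$r * sd(as.vector(x))
    if (r == 0) r <- cfg$r # constant input: any positive threshold gives phi = 1
  }
  cfg_scale <- cfg; cfg_scale$r <- r; cfg_scale$normalize <- FALSE

  res <- purrr::map(scales, function(tau) {
    offsets <- if (cfg$variant == "mvMFE") 1L else seq_len(tau)
    grades <- matrix(NA_real_, length(offsets), 2L)
    for (ki in seq_along(offsets)) {
      k <- offsets[ki]
      n_out <- (ncol(x) - k + 1L) %/% tau
      if (n_out - max(m) * max(lam) < 2L) break
      y <- t(apply(x, 1L, coarse_grain, tau = tau, k_offset = k))
      if (p == 1L) y <- matrix(y, nrow = 1L)
      grades[ki, ] <- mv_fuzzy_entropy(y, cfg_scale)
    }
    if (anyNA(grades)) {
      return(tibble(scale = tau, entropy = NA_real_, valid = FALSE,
                    phi_m = NA_real_, phi_m1 = NA_real_))
    }
    phi_m <- mean(grades[, 1L]); phi_m1 <- mean(grades[, 2L])
    if (phi_m <= 0 || phi_m1 <= 0) {
      return(tibble(scale = tau, entropy = NA_real_, valid = FALSE,
                    phi_m = phi_m, phi_m1 = phi_m1))
    }
    tibble(scale = tau, entropy = -log(phi_m1 / phi_m), valid = TRUE,
           phi_m = phi_m, phi_m1 = phi_m1)
  })
  dplyr::bind_rows(res)
}
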