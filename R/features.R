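#' Per-trial multiscale entropy features
#'
#' Runs [entropy_profile()] on every trial and assembles the trials x scales
#' feature matrix used for classification: one row per trial, one column per
#' scale factor, plus the class label. Invalid scales become `NA` cells (and
#' a warning reports how many).
#'
#' @param epochs an [epoch_set()]; all trials share length and channels.
#' @param cfg an [entropy_config()].
#' @return A tibble of class `mvmfe_features` with columns `trial`, `label`
#'   and `scale_1 .. scale_<scale_max>`.
#' @export
build_features <- function(epochs, cfg = entropy_config()) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(cfg, "entropy_config"))
  prof <- purrr::map(seq_len(n_trials(epochs)), function(t) {
    p <- entropy_profile(trial_matrix(epochs, t), cfg)
    p$trial <- t
    p
  })
  prof <- dplyr::bind_rows(prof)
  n_bad <- sum(!prof$valid)
  if (n_bad > 0L) {
    warn(sprintf("%d of %d (trial, scale) cells are invalid and set to NA",
                 n_bad, nrow(prof)))
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(prof, "trial", "scale", "entropy"),
    names_from = "scale", values_from = "entropy", names_prefix = "scale_"
  )
  out <- dplyr::bind_cols(
    tibble(trial = wide$trial, label = epochs$labels[wide$trial]),
    dplyr::select(wide, -"trial")
  )
  class(out) <- c("mvmfe_features", class(out))
  out
}

feature_cols <- function(features) {
  grep("^scale_[0-9]+$", names(features), value = TRUE)
}

#' Class-mean entropy curves across scales
#'
#' @param features a feature tibble from [build_features()].
#' @return A ggplot of per-class mean entropy (with +/- 1 SD ribbons) versus
#'   scale factor.
#' @export
plot_entropy_profiles <- function(features) {
  long <- tidyr::pivot_longer(features, dplyr::all_of(feature_cols(features)),
                              names_to = "scale", values_to = "entropy")
  long$scale <- as.integer(sub("^scale_", "", long$scale))
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$label, .data$scale),
    mean = mean(.data$entropy, na.rm = TRUE),
    sd = sd(.data$entropy, na.rm = TRUE), .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(.data$scale, .data$mean,
                                     colour = factor(.data$label),
                                     fill = factor(.data$label))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "scale factor", y = "entropy", colour = "class",
                  fill = "class") +
    ggplot2::theme_minimal()
}
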