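#' Cohen's kappa from accuracy and chance agreement
#'
#' `kappa = (p0 - pe) / (1 - pe)`. For a balanced two-class design
#' `pe = 0.5`, so `kappa = 2 * p0 - 1`.
#'
#' @param p0 observed accuracy in `[0, 1]`.
#' @param pe chance agreement in `[0, 1)`.
#' @return Scalar kappa.
#' @examples
#' cohen_kappa(0.7554) # 0.5108
#' @export
cohen_kappa <- function(p0, pe = 0.5) {
  if (any(p0 < 0 | p0 > 1)) stop_param("`p0` must lie in [0, 1]")
  if (any(pe < 0 | pe >= 1)) stop_param("`pe` must lie in [0, 1)")
  (p0 - pe) / (1 - pe)
}

# stratified fold ids: within each class, trials are shuffled and folds are
# dealt round-robin, so per-fold class imbalance is at most one trial
stratified_folds <- function(labels, folds) {
  ids <- integer(length(labels))
  for (cls in unique(labels)) {
    i <- which(labels == cls)
    i <- i[sample.int(length(i))]
    ids[i] <- rep_len(seq_len(folds), length(i))
  }
  ids
}

# min-max scaling to [0, 1] with statistics from the training rows only;
# zero-range columns collapse to 0 everywhere
minmax_fit <- function(train) {
  list(lo = apply(train, 2L, min), hi = apply(train, 2L, max))
}
minmax_apply <- function(x, fit) {
  rng <- fit$hi - fit$lo
  rng[rng == 0] <- Inf
  sweep(sweep(x, 2L, fit$lo, "-"), 2L, rng, "/")
}

# fit/evaluate one outer fold: scale from training rows, nested grid search
# on training rows only, then train with the winning pair and score the test
# rows. Exposed internally so leakage properties can be tested directly.
svm_eval_fold <- function(x_train, y_train, x_test, y_test,
                          cost_grid, gamma_grid, inner_folds) {
  fit <- minmax_fit(x_train)
  xtr <- minmax_apply(x_train, fit)
  xte <- minmax_apply(x_test, fit)
  ytr <- factor(y_train, levels = c(1, 2))

  best <- c(NA_real_, NA_real_); best_acc <- -1
  inner_ids <- stratified_folds(y_train, inner_folds)
  for (cost in cost_grid) {
    for (gamma in gamma_grid) {
      accs <- numeric(inner_folds)
      for (f in seq_len(inner_folds)) {
        tr <- inner_ids != f
        if (length(unique(y_train[tr])) < 2L) { accs[f] <- 0; next }
        mod <- e1071::svm(xtr[tr, , drop = FALSE], ytr[tr], kernel = "radial",
                          cost = cost, gamma = gamma, scale = FALSE)
        pred <- predict(mod, xtr[!tr, , drop = FALSE])
        accs[f] <- mean(pred == ytr[!tr])
      }
      acc <- mean(accs)
      if (acc > best_acc + 1e-12) { # strict improvement: first-listed pair wins ties
        best_acc <- acc; best <- c(cost, gamma)
      }
    }
  }
  mod <- e1071::svm(xtr, ytr, kernel = "radial", cost = best[1],
                    gamma = best[2], scale = FALSE)
  pred <- predict(mod, xte)
  list(accuracy = mean(pred == factor(y_test, levels = c(1, 2))),
       cost = best[1], gamma = best[2])
}

#' Repeated stratified cross-validation with a Gaussian-kernel SVM
#'
#' The evaluation protocol for multiscale entropy features: `repeats`
#' independent stratified `folds`-fold partitions (reshuffled per repeat from
#' `seed`). Within every training fold the features are min-max scaled to
#' `[0, 1]` and the SVM cost / kernel-width pair is chosen by an inner
#' stratified grid search -- both using training data only, so no information
#' leaks from the held-out fold. Accuracy is measured on the held-out fold;
#' all `repeats * folds` fold accuracies are retained, and kappa is computed
#' from the mean accuracy with chance agreement 0.5 (balanced two-class
#' design).
#'
#' Trials with any `NA` feature (invalid entropy scale) are dropped with a
#' message.
#'
#' @param features feature tibble from [build_features()] (columns `label`
#'   and `scale_*`).
#' @param repeats,folds protocol size; the conventional choice is 10 x 10.
#' @param seed integer seed controlling every shuffle.
#' @param cost_grid,gamma_grid exponential hyperparameter grids for the SVM
#'   margin penalty and Gaussian kernel width.
#' @param inner_folds folds of the nested grid-search CV.
#' @return An object of class `mvmfe_eval`; see [tidy.mvmfe_eval()] /
#'   [glance.mvmfe_eval()].
#' @export
crossvalidate <- function(features, repeats = 10, folds = 10, seed = 1,
                          cost_grid = 2^seq(-5, 15, by = 5),
                          gamma_grid = 2^seq(-15, 3, by = 6),
                          inner_folds = 5) {
  cols <- feature_cols(features)
  if (length(cols) == 0L) stop_param("`features` has no scale_* columns")
  keep <- stats::complete.cases(features[, cols])
  if (!all(keep)) {
    message(sprintf("dropping %d trial(s) with invalid feature cells", sum(!keep)))
    features <- features[keep, ]
  }
  y <- features$label
  if (length(unique(y)) < 2L) stop_data("cross-validation needs both classes present")
  if (min(table(y)) < folds) {
    stop_data(sprintf("need >= %d trials per class for %d folds", folds, folds))
  }
  x <- as.matrix(features[, cols])

  res <- withr::with_seed(as.integer(seed), {
    rows <- vector("list", repeats * folds)
    i <- 1L
    for (rep_i in seq_len(repeats)) {
      fold_ids <- stratified_folds(y, folds)
      for (f in seq_len(folds)) {
        te <- fold_ids == f
        ev <- svm_eval_fold(x[!te, , drop = FALSE], y[!te],
                            x[te, , drop = FALSE], y[te],
                            cost_grid, gamma_grid, inner_folds)
        rows[[i]] <- tibble(repeat_id = rep_i, fold = f,
                            accuracy = ev$accuracy, cost = ev$cost,
                            gamma = ev$gamma)
        i <- i + 1L
      }
    }
    dplyr::bind_rows(rows)
  })

  mean_acc <- mean(res$accuracy)
  hp <- dplyr::count(res, .data$cost, .data$gamma, sort = TRUE)
  structure(
    list(
      folds = res,
      mean_accuracy = mean_acc,
      sd_accuracy = sd(res$accuracy),
      kappa = cohen_kappa(mean_acc, 0.5),
      best_hyperparams = list(cost = hp$cost[1], gamma = hp$gamma[1]),
      n_trials = length(y), n_features = length(cols),
      repeats = repeats, n_folds = folds, seed = as.integer(seed)
    ),
    class = "mvmfe_eval"
  )
}

#' @export
print.mvmfe_eval <- function(x, ...) {
  cat(sprintf(
    "<mvmfe_eval> %d x %d-fold CV on %d trials, %d features\n",
    x$repeats, x$n_folds, x$n_trials, x$n_features
  ))
  cat(sprintf("  accuracy: %.2f%% +/- %.2f%%   kappa: %.4f\n",
              100 * x$mean_accuracy, 100 * x$sd_accuracy, x$kappa))
  cat(sprintf("  modal hyperparameters: cost = %g, gamma = %g\n",
              x$best_hyperparams$cost, x$best_hyperparams$gamma))
  invisible(x)
}

#' Tidy the per-fold results of a CV report
#'
#' @param x an `mvmfe_eval` from [crossvalidate()].
#' @param ... unused.
#' @return Tibble with one row per held-out fold: `repeat_id`, `fold`,
#'   `accuracy`, and the selected `cost` / `gamma`.
#' @export
tidy.mvmfe_eval <- function(x, ...) x$folds

#' One-row summary of a CV report
#'
#' @param x an `mvmfe_eval` from [crossvalidate()].
#' @param ... unused.
#' @return One-row tibble: `mean_accuracy`, `sd_accuracy`, `kappa`,
#'   `n_folds_total`, `n_trials`, `n_features`.
#' @export
glance.mvmfe_eval <- function(x, ...) {
  tibble(
    mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
    kappa = x$kappa, n_folds_total = nrow(x$folds),
    n_trials = x$n_trials, n_features = x$n_features
  )
}

#' @export
autoplot.mvmfe_eval <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(factor(.data$repeat_id), .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = 2) +
    ggplot2::labs(x = "repeat", y = "held-out fold accuracy") +
    ggplot2::theme_minimal()
}

#' Average evaluation reports across subjects
#'
#' Arithmetic means across reports of the mean accuracy, its standard
#' deviation and kappa, the way multi-subject studies report an "average
#' results" row. Accuracies are displayed in percent.
#'
#' @param reports list of `mvmfe_eval` objects (or numeric accuracy values in
#'   `[0, 1]`, for which kappa is derived with chance agreement 0.5).
#' @return One-row tibble: `n_subjects`, `mean_accuracy_pct` (2 decimals),
#'   `mean_sd_pct` (2 decimals), `mean_kappa` (4 decimals).
#' @export
summarize_reports <- function(reports) {
  if (length(reports) == 0L) stop_param("need at least one report")
  if (inherits(reports, "mvmfe_eval")) reports <- list(reports)
  acc <- vapply(reports, function(r) {
    if (inherits(r, "mvmfe_eval")) r$mean_accuracy else as.numeric(r)
  }, numeric(1))
  sds <- vapply(reports, function(r) {
    if (inherits(r, "mvmfe_eval")) r$sd_accuracy else NA_real_
  }, numeric(1))
  kap <- vapply(reports, function(r) {
    if (inherits(r, "mvmfe_eval")) r$kappa else cohen_kappa(as.numeric(r), 0.5)
  }, numeric(1))
  tibble(
    n_subjects = length(reports),
    mean_accuracy_pct = round(mean(acc) * 100, 2),
    mean_sd_pct = round(mean(sds) * 100, 2),
    mean_kappa = round(mean(kap), 4)
  )
}
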