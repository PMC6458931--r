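make_features <- function(n_per_class, sep, noise_sd = 0.1, seed = 1, p = 4) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    labels <- rep_len(c(1L, 2L), n)
    mu <- ifelse(labels == 1, -sep / 2, sep / 2)
    x <- matrix(rnorm(n * p, mean = mu, sd = noise_sd), nrow = n)
    out <- tibble::as_tibble(as.data.frame(x))
    names(out) <- paste0("scale_", seq_len(p))
    out <- dplyr::bind_cols(tibble::tibble(trial = seq_len(n), label = labels), out)
    class(out) <- c("mvmfe_features", class(out))
    out
  })
}

small_grid <- list(cost_grid = 2^c(0, 5), gamma_grid = 2^c(-7, -3, 0))

test_that("cohen_kappa follows its closed form and matches published cells", {
  expect_equal(cohen_kappa(0.7554, 0.5), 0.5108)
  expect_equal(cohen_kappa(0.5, 0.5), 0)
  expect_equal(cohen_kappa(1, 0.9), 1)
  expect_equal(cohen_kappa(0.25, 0), 0.25)
  expect_error(cohen_kappa(1.2), class = "mvmfe_param_error")
  expect_error(cohen_kappa(0.5, 1), class = "mvmfe_param_error")

  # affine bijection at pe = 0.5, checked against consistent benchmark cells
  bench <- readr::read_tsv(
    system.file("extdata", "benchmark_multivariate_entropy.tsv", package = "mvmfe"),
    show_col_types = FALSE
  )
  derived <- cohen_kappa(bench$accuracy_pct / 100, 0.5)
  consistent <- abs(derived - bench$kappa_printed) < 5e-4
  expect_gte(sum(consistent), 10) # most cells are internally consistent
  expect_equal(derived[consistent], bench$kappa_printed[consistent],
               tolerance = 5e-4)
  expect_equal(derived, 2 * bench$accuracy_pct / 100 - 1)
})

test_that("summarize_reports reproduces multi-subject average rows", {
  acc <- c(75.54, 86.00, 74.46, 84.07, 79.32) / 100
  expect_equal(summarize_reports(as.list(acc))$mean_accuracy_pct, 79.88)
  kappas <- c(0.5108, 0.7200, 0.4928, 0.6814, 0.5864)
  expect_equal(round(mean(kappas), 4), 0.5983)
  expect_error(summarize_reports(list()), class = "mvmfe_param_error")
})

test_that("well-separated features classify near perfectly and deterministically", {
  feats <- make_features(15, sep = 20, noise_sd = 0.1)
  rep1 <- do.call(crossvalidate, c(list(feats, repeats = 3, folds = 10, seed = 5),
                                   small_grid))
  expect_gte(rep1$mean_accuracy, 0.99)
  expect_equal(rep1$kappa, 2 * rep1$mean_accuracy - 1)
  expect_equal(nrow(rep1$folds), 30)
  expect_equal(rep1$mean_accuracy, mean(rep1$folds$accuracy))
  expect_equal(rep1$sd_accuracy, sd(rep1$folds$accuracy))

  rep2 <- do.call(crossvalidate, c(list(feats, repeats = 3, folds = 10, seed = 5),
                                   small_grid))
  expect_identical(rep1$folds, rep2$folds)
  # with overlapping classes, fold accuracies respond to the fold shuffle
  hard <- make_features(15, sep = 2, noise_sd = 1.5, seed = 4)
  h1 <- do.call(crossvalidate, c(list(hard, repeats = 2, folds = 10, seed = 5),
                                 small_grid))
  h2 <- do.call(crossvalidate, c(list(hard, repeats = 2, folds = 10, seed = 6),
                                 small_grid))
  expect_false(identical(h1$folds$accuracy, h2$folds$accuracy))
})

test_that("tidy/glance/autoplot expose the report", {
  feats <- make_features(10, sep = 6)
  rep <- do.call(crossvalidate, c(list(feats, repeats = 2, folds = 5, seed = 2),
                                  small_grid))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("repeat_id", "fold", "accuracy", "cost", "gamma"))
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mean_accuracy, rep$mean_accuracy)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("stratified folds are balanced within one trial", {
  labels <- rep_len(c(1L, 2L), 50)
  withr::with_seed(3, {
    for (i in 1:10) {
      ids <- mvmfe:::stratified_folds(labels, 10)
      per_fold <- table(ids, labels)
      expect_true(all(abs(per_fold[, 1] - per_fold[, 2]) <= 1))
      expect_true(all(table(ids) %in% c(4, 5, 6)))
    }
  })
})

test_that("held-out data cannot leak through scaling or grid search", {
  # a canary feature that is constant in training but label-valued in the
  # held-out fold must not change the fold accuracy
  feats <- make_features(10, sep = 2, noise_sd = 1.5, seed = 11)
  x <- as.matrix(feats[, paste0("scale_", 1:4)])
  y <- feats$label
  te <- seq_len(20) <= 6
  base <- withr::with_seed(1, mvmfe:::svm_eval_fold(
    x[!te, ], y[!te], x[te, ], y[te], 2^c(0, 5), 2^c(-7, 0), 3
  ))
  canary_tr <- cbind(x[!te, ], canary = 0)
  canary_te <- cbind(x[te, ], canary = y[te])
  canary <- withr::with_seed(1, mvmfe:::svm_eval_fold(
    canary_tr, y[!te], canary_te, y[te], 2^c(0, 5), 2^c(-7, 0), 3
  ))
  expect_equal(canary$accuracy, base$accuracy)
  expect_equal(canary$cost, base$cost)
})

test_that("degenerate inputs are rejected", {
  feats <- make_features(12, sep = 5)
  one_class <- feats[feats$label == 1, ]
  expect_error(crossvalidate(one_class, repeats = 2, folds = 5),
               class = "mvmfe_data_error")
  expect_error(crossvalidate(feats, repeats = 2, folds = 20),
               class = "mvmfe_data_error")
  no_scales <- feats[, c("trial", "label")]
  expect_error(crossvalidate(no_scales), class = "mvmfe_param_error")
})

test_that("trials with invalid feature cells are dropped with a message", {
  feats <- make_features(8, sep = 10)
  feats$scale_2[3] <- NA
  expect_message(
    rep <- do.call(crossvalidate, c(list(feats, repeats = 2, folds = 5, seed = 9),
                                    small_grid)),
    "dropping 1"
  )
  expect_equal(rep$n_trials, 15)
})
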