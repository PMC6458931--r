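#' Pipeline run configuration
#'
#' Bundles every stage parameter of the standard analysis flow: read ->
#' band-pass -> segment -> channel selection -> multiscale entropy features
#' -> repeated cross-validation. Fully serializable to YAML so a run can be
#' reproduced from the config written next to its outputs.
#'
#' @param input path of an on-disk epoch set (see [read_epochs()]); may be
#'   `NULL` when an `epoch_set` is passed to [run_pipeline()] directly.
#' @param layout input layout, `"delimited_dir"` or `"single_table"`.
#' @param band length-2 band-pass edges in Hz, or `NULL` to skip filtering.
#' @param segment length-2 1-based inclusive sample interval, or `NULL`.
#' @param channels explicit channel whitelist (names or indices), or `NULL`
#'   to rank channels by Fisher score instead.
#' @param top_k number of top-scoring channels to keep when `channels` is
#'   `NULL`; `NULL` keeps all channels.
#' @param entropy an [entropy_config()].
#' @param cv list with `repeats`, `folds`, `seed`.
#' @param out_dir artifact directory, or `NULL` for no files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, layout = "delimited_dir", band = c(8, 32),
                       segment = NULL, channels = NULL, top_k = NULL,
                       entropy = entropy_config(),
                       cv = list(repeats = 10, folds = 10, seed = 1),
                       out_dir = NULL) {
  stopifnot(inherits(entropy, "entropy_config"))
  cv <- utils::modifyList(list(repeats = 10, folds = 10, seed = 1), cv)
  structure(
    list(input = input, layout = layout, band = band, segment = segment,
         channels = channels, top_k = top_k, entropy = entropy, cv = cv,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- unclass(config)
  lst$entropy <- unclass(config$entropy)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  lst <- yaml::read_yaml(path)
  ent <- lst$entropy %||% list()
  run_config(
    input = lst$input, layout = lst$layout %||% "delimited_dir",
    band = unlist(lst$band), segment = unlist(lst$segment),
    channels = unlist(lst$channels), top_k = lst$top_k,
    entropy = do.call(entropy_config, ent),
    cv = lst$cv %||% list(), out_dir = lst$out_dir
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (band-pass, segmentation, channel selection,
#' per-trial multiscale entropy features, repeated stratified SVM
#' cross-validation) and, when `config$out_dir` is set, writes the channel
#' scores, feature matrix, evaluation report (JSON, with all fold
#' accuracies), the effective config and the package version next to each
#' other.
#'
#' @param config a [run_config()].
#' @param epochs optionally, an in-memory [epoch_set()]; otherwise
#'   `config$input` is read from disk.
#' @return An object of class `mvmfe_pipeline`: list with `report`
#'   (`mvmfe_eval`), `scores` (tibble or `NULL`), `features`, `channels_used`
#'   and `config`.
#' @export
run_pipeline <- function(config, epochs = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(epochs)) {
    if (is.null(config$input)) stop_param("config has no `input` and no epochs were given")
    epochs <- read_epochs(config$input, config$layout)
  }
  if (!is.null(config$band)) {
    epochs <- bandpass(epochs, config$band[1], config$band[2])
  }
  if (!is.null(config$segment)) {
    epochs <- segment_epochs(epochs, config$segment[1], config$segment[2])
  }
  scores <- NULL
  if (!is.null(config$channels)) {
    epochs <- subset_channels(epochs, config$channels)
    used <- epochs$channel_names
  } else if (!is.null(config$top_k)) {
    band <- config$band %||% c(8, 32)
    scores <- fisher_scores(epochs, band)
    idx <- select_channels(scores, config$top_k)
    epochs <- subset_channels(epochs, idx)
    used <- epochs$channel_names
  } else {
    used <- epochs$channel_names
  }
  features <- build_features(epochs, config$entropy)
  report <- crossvalidate(features, repeats = config$cv$repeats,
                          folds = config$cv$folds, seed = config$cv$seed)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(scores)) {
      readr::write_csv(scores, file.path(config$out_dir, "channel_scores.csv"),
                       progress = FALSE)
    }
    readr::write_csv(features, file.path(config$out_dir, "features.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(mean_accuracy = report$mean_accuracy,
           sd_accuracy = report$sd_accuracy, kappa = report$kappa,
           best_hyperparams = report$best_hyperparams,
           channels_used = used, fold_accuracies = report$folds$accuracy),
      file.path(config$out_dir, "eval_report.json"),
      auto_unbox = TRUE, digits = NA
    )
    write_run_config(config, file.path(config$out_dir, "effective_config.yaml"))
    writeLines(as.character(utils::packageVersion("mvmfe")),
               file.path(config$out_dir, "VERSION"))
  }
  structure(
    list(report = report, scores = scores, features = features,
         channels_used = used, config = config),
    class = "mvmfe_pipeline"
  )
}

#' @export
print.mvmfe_pipeline <- function(x, ...) {
  cat("<mvmfe_pipeline> channels used: ", paste(x$channels_used, collapse = ", "),
      "\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Accuracy as a function of the maximum scale factor
#'
#' Repeats the cross-validated evaluation with the feature vector truncated
#' to each candidate maximum scale, so the user can pick the scale range
#' (the accuracy-versus-scale sweep used to choose `scale_max`). Features
#' are computed once at `max(scale_range)` and truncated per candidate; no
#' automatic optimum is chosen.
#'
#' @param config a [run_config()]; `config$entropy$scale_max` is raised to
#'   `max(scale_range)` if needed.
#' @param scale_range integer vector of candidate maximum scales.
#' @param epochs optional in-memory [epoch_set()].
#' @return Tibble with columns `tau_max`, `mean_accuracy`, `sd_accuracy`,
#'   `kappa`.
#' @export
scale_sweep <- function(config, scale_range, epochs = NULL) {
  stopifnot(inherits(config, "run_config"))
  scale_range <- as.integer(scale_range)
  if (length(scale_range) == 0L) stop_param("`scale_range` must not be empty")
  if (any(scale_range < 1L)) stop_param("`scale_range` values must be >= 1")
  cfg <- config$entropy
  cfg$scale_max <- max(max(scale_range), cfg$scale_max)

  if (is.null(epochs)) {
    if (is.null(config$input)) stop_param("config has no `input` and no epochs were given")
    epochs <- read_epochs(config$input, config$layout)
  }
  if (!is.null(config$band)) epochs <- bandpass(epochs, config$band[1], config$band[2])
  if (!is.null(config$segment)) {
    epochs <- segment_epochs(epochs, config$segment[1], config$segment[2])
  }
  if (!is.null(config$channels)) {
    epochs <- subset_channels(epochs, config$channels)
  } else if (!is.null(config$top_k)) {
    idx <- select_channels(fisher_scores(epochs, config$band %||% c(8, 32)),
                           config$top_k)
    epochs <- subset_channels(epochs, idx)
  }
  features <- build_features(epochs, cfg)
  purrr::map_dfr(scale_range, function(tmax) {
    keep <- c("trial", "label", paste0("scale_", seq_len(tmax)))
    sub <- features[, intersect(keep, names(features))]
    class(sub) <- class(features)
    rep <- crossvalidate(sub, repeats = config$cv$repeats,
                         folds = config$cv$folds, seed = config$cv$seed)
    tibble(tau_max = tmax, mean_accuracy = rep$mean_accuracy,
           sd_accuracy = rep$sd_accuracy, kappa = rep$kappa)
  })
}
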