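#' Read an epoch set from disk
#'
#' Two plain-text layouts are supported. `delimited_dir` holds one file per
#' trial (`trial_0001.txt`, ... — rows are channels, columns are samples,
#' comma- or tab-delimited), a `labels.txt` with one integer label per line,
#' and a `meta.yaml` with `fs` and `channel_names`. `single_table` holds one
#' delimited file `epochs.csv` with columns `trial, channel, sample_index,
#' value` plus the same `labels.txt` / `meta.yaml`.
#'
#' @param path directory containing the files.
#' @param layout `"delimited_dir"` or `"single_table"`.
#' @return An [epoch_set()]; trial order is as on disk.
#' @seealso [write_epochs()]
#' @export
read_epochs <- function(path, layout = c("delimited_dir", "single_table")) {
  layout <- match.arg(layout)
  if (!dir.exists(path)) stop_io(sprintf("path does not exist: %s", path))
  meta_file <- file.path(path, "meta.yaml")
  labels_file <- file.path(path, "labels.txt")
  for (f in c(meta_file, labels_file)) {
    if (!file.exists(f)) stop_format(sprintf("missing required file: %s", f))
  }
  meta <- yaml::read_yaml(meta_file)
  if (is.null(meta$fs)) stop_format(sprintf("meta.yaml lacks `fs`: %s", meta_file))
  labels <- suppressWarnings(as.integer(readLines(labels_file)))
  if (length(labels) == 0L || anyNA(labels)) {
    stop_format(sprintf("labels.txt is empty or non-integer: %s", labels_file))
  }

  if (layout == "delimited_dir") {
    files <- sort(list.files(path, pattern = "^trial_[0-9]+\\.txt$",
                             full.names = TRUE))
    if (length(files) == 0L) {
      stop_format(sprintf("no trial_*.txt files found in %s", path))
    }
    if (length(files) != length(labels)) {
      stop_format(sprintf(
        "%d trial files but %d labels in %s", length(files), length(labels), path
      ))
    }
    mats <- lapply(files, read_trial_matrix)
    dims <- vapply(mats, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
      stop_format(sprintf(
        "ragged trial file (%dx%d, expected %dx%d): %s",
        dims[1, bad], dims[2, bad], dims[1, 1], dims[2, 1], files[bad]
      ))
    }
    arr <- array(0, dim = c(length(mats), dims[1, 1], dims[2, 1]))
    for (t in seq_along(mats)) arr[t, , ] <- mats[[t]]
  } else {
    tab_file <- file.path(path, "epochs.csv")
    if (!file.exists(tab_file)) stop_format(sprintf("missing file: %s", tab_file))
    # value is parsed via strtod (as.numeric) so serialized doubles
    # round-trip bit-exactly
    tab <- readr::read_csv(tab_file, col_types = readr::cols(
      trial = readr::col_integer(), channel = readr::col_integer(),
      sample_index = readr::col_integer(), value = readr::col_character()
    ), progress = FALSE)
    if (nrow(tab) == 0L) stop_format(sprintf("empty table: %s", tab_file))
    tab$value <- suppressWarnings(as.numeric(tab$value))
    if (anyNA(tab)) {
      bad <- which(!stats::complete.cases(tab))[1]
      stop_format(sprintf("non-numeric or missing cell at row %d of %s", bad, tab_file))
    }
    nt <- max(tab$trial); nc <- max(tab$channel); ns <- max(tab$sample_index)
    if (nrow(tab) != nt * nc * ns) {
      stop_format(sprintf("table is not a complete trial/channel/sample grid: %s", tab_file))
    }
    arr <- array(NA_real_, dim = c(nt, nc, ns))
    arr[cbind(tab$trial, tab$channel, tab$sample_index)] <- tab$value
  }
  epoch_set(arr, labels, fs = meta$fs, channel_names = meta$channel_names)
}

read_trial_matrix <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_format(sprintf("empty trial file: %s", file))
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  rows <- strsplit(lines, sep, fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != lens[1])) {
    stop_format(sprintf("ragged rows in %s (row %d has %d cells, expected %d)",
                        file, which(lens != lens[1])[1],
                        lens[which(lens != lens[1])[1]], lens[1]))
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop_format(sprintf("non-numeric cell in %s at row %d, column %d",
                        file, (bad - 1) %/% lens[1] + 1, (bad - 1) %% lens[1] + 1))
  }
  matrix(vals, nrow = length(rows), byrow = TRUE)
}

#' Write an epoch set to disk
#'
#' Values are serialized with 17 significant digits so a
#' [read_epochs()] round trip is bit-identical.
#'
#' @param epochs an [epoch_set()].
#' @param path output directory (created if needed).
#' @param layout `"delimited_dir"` or `"single_table"`; see [read_epochs()].
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path, layout = c("delimited_dir", "single_table")) {
  layout <- match.arg(layout)
  stopifnot(inherits(epochs, "epoch_set"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(path, mode = 2L) != 0L) {
    stop_io(sprintf("cannot write to %s", path))
  }
  fmt <- function(x) sprintf("%.17g", x)
  if (layout == "delimited_dir") {
    for (t in seq_len(n_trials(epochs))) {
      m <- trial_matrix(epochs, t)
      lines <- apply(m, 1L, function(row) paste(fmt(row), collapse = ","))
      writeLines(lines, file.path(path, sprintf("trial_%04d.txt", t)))
    }
  } else {
    d <- dim(epochs$data)
    idx <- expand.grid(trial = seq_len(d[1]), channel = seq_len(d[2]),
                       sample_index = seq_len(d[3]))
    tab <- tibble(
      trial = idx$trial, channel = idx$channel, sample_index = idx$sample_index,
      value = fmt(epochs$data[cbind(idx$trial, idx$channel, idx$sample_index)])
    )
    tab <- dplyr::arrange(tab, .data$trial, .data$channel, .data$sample_index)
    readr::write_csv(tab, file.path(path, "epochs.csv"), progress = FALSE)
  }
  writeLines(as.character(epochs$labels), file.path(path, "labels.txt"))
  yaml::write_yaml(
    list(fs = epochs$fs, channel_names = as.list(epochs$channel_names)),
    file.path(path, "meta.yaml")
  )
  invisible(path)
}
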