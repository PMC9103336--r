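# Readers and writers for recordings, annotations and feature tables, plus
# the end-to-end pipeline driver. Recordings are exchanged as plain CSV
# (columns M, A1, A2, A3), annotations as one-sample-index-per-line text
# sidecars, and per-recording metadata (sampling rate, label) as JSON.

#' Write a recording to disk
#'
#' Creates `<id>.csv` (waveforms, full precision), `<id>.mqrs.txt` and
#' `<id>.fqrs.txt` (one sample index per line) and `<id>.meta.json`
#' (id, fs, label, metadata) in `dir`.
#'
#' @param recording an `fecg_recording`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the path of the waveform CSV.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "fecg_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, recording$id)
  utils::write.csv(as.data.frame(recording$channels),
                   paste0(base, ".csv"), row.names = FALSE)
  writeLines(as.character(recording$mqrs), paste0(base, ".mqrs.txt"))
  writeLines(as.character(recording$fqrs), paste0(base, ".fqrs.txt"))
  meta <- c(list(id = recording$id, fs = recording$fs,
                 label = recording$label), recording$meta)
  jsonlite::write_json(meta, paste0(base, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(base, ".csv"))
}

#' Read a recording from disk
#'
#' Reads the CSV waveform file plus any annotation/metadata sidecars
#' written by [write_recording()].
#'
#' @param path path to the waveform CSV.
#' @param format `"csv"`; `"wfdb"` is recognised but not supported in this
#'   implementation and raises an error.
#' @param fs sampling rate fallback when no metadata sidecar exists.
#' @return An `fecg_recording`.
#' @export
read_recording <- function(path, format = c("csv", "wfdb"), fs = 1000) {
  format <- match.arg(format)
  if (format == "wfdb") {
    stop("WFDB input is not supported by this implementation; convert to CSV")
  }
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path)
  if (ncol(df) != 4L) {
    stop(sprintf("%s: expected 4 channel columns (M, A1, A2, A3), found %d",
                 path, ncol(df)))
  }
  if (!all(c("M", "A1", "A2", "A3") %in% names(df))) {
    stop(sprintf("%s: channel columns must be named M, A1, A2, A3", path))
  }
  base <- sub("\\.csv$", "", path)
  read_ann <- function(p) {
    if (!file.exists(p)) return(integer())
    v <- as.integer(readLines(p))
    v[!is.na(v)]
  }
  mqrs <- read_ann(paste0(base, ".mqrs.txt"))
  fqrs <- read_ann(paste0(base, ".fqrs.txt"))
  label <- "unknown"; id <- basename(base); meta <- list()
  mp <- paste0(base, ".meta.json")
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    fs <- meta$fs %||% fs
    label <- meta$label %||% label
    id <- meta$id %||% id
    meta <- meta[setdiff(names(meta), c("id", "fs", "label"))]
  }
  fecg_recording(as.matrix(df[, c("M", "A1", "A2", "A3")]), fs,
                 mqrs, fqrs, label, id, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset with its manifest
#'
#' Writes every recording via [write_recording()] and a `manifest.csv`
#' with columns id, label, snr_db, fhr_bpm, mhr_bpm, seed.
#'
#' @param recordings list of `fecg_recording`.
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(recordings, dir) {
  for (r in recordings) write_recording(r, dir)
  manifest <- do.call(rbind, lapply(recordings, function(r) {
    data.frame(id = r$id, label = r$label,
               snr_db = r$meta$target_foetal_snr_db %||% NA_real_,
               fhr_bpm = r$meta$fhr_bpm %||% NA_real_,
               mhr_bpm = r$meta$mhr_bpm %||% NA_real_,
               seed = r$meta$seed %||% NA_integer_)
  }))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset directory
#'
#' @param dir directory written by [write_dataset()].
#' @return List of `fecg_recording`.
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(manifest$id, function(id) {
    read_recording(file.path(dir, paste0(id, ".csv")))
  })
}

#' Run the end-to-end quality-assessment pipeline
#'
#' Generates (or loads) a dataset, preprocesses every recording, trains and
#' evaluates the requested learner under nested stratified CV, and writes a
#' machine-readable JSON summary with metric aggregates, confusion totals,
#' per-minute error rates and recording-level majority votes.
#'
#' @param config list with elements:
#'   `synth` (list: n_good, n_bad, duration_s, seed) or `data_dir`;
#'   `learner` (`"cnn"`, `"nb"`, `"svm_linear"`, `"svm_rbf"`, `"rf"`);
#'   `arch` (`arch_config`, cnn only), `train` (`train_config`, cnn only);
#'   `folds` (`fold_spec`); `out_dir` (optional, for the JSON summary).
#' @return The summary list, invisibly written to
#'   `file.path(out_dir, "summary.json")` when `out_dir` is given.
#' @export
run_pipeline <- function(config) {
  recs <- if (!is.null(config$data_dir)) {
    read_dataset(config$data_dir)
  } else {
    sy <- config$synth
    base <- synth_config(duration_s = sy$duration_s %||% 60)
    generate_dataset(sy$n_good, sy$n_bad, base, seed = sy$seed %||% 1L)
  }
  spec <- config$folds %||% fold_spec()
  pp <- lapply(recs, preprocess_recording)
  segs <- do.call(c, lapply(pp, `[[`, "segments"))
  labels <- vapply(segs, `[[`, character(1), "label")
  rec_ids <- vapply(segs, `[[`, character(1), "recording_id")
  seg_seconds <- length(segs) * 2.5

  if (identical(config$learner, "cnn")) {
    imgs <- do.call(c, lapply(pp, `[[`, "images"))
    arch <- config$arch %||% arch_config()
    chans <- if (arch$n_paths == 4L) c("M", "A1", "A2", "A3") else
      c("A1", "A2", "A3")
    data <- list(X = stack_images(imgs, chans), y = labels,
                 recording_id = rec_ids)
    learner <- learner_cnn(arch, config$train %||% train_config())
  } else {
    ft <- feature_table(segs)
    data <- list(X = as.matrix(ft[, sqi_feature_names()]), y = labels,
                 recording_id = rec_ids)
    learner <- learner_classical(grid_spec(config$learner))
  }
  res <- nested_cv(data, learner, spec)
  rates <- error_rate_per_minute(res$confusion[["fp"]], res$confusion[["fn"]],
                                 seg_seconds / 60 * spec$repetitions)
  summary <- list(
    learner = learner$name,
    n_recordings = length(recs), n_segments = length(segs),
    folds = list(outer_k = spec$outer_k, inner_k = spec$inner_k,
                 repetitions = spec$repetitions, seed = spec$seed),
    aggregate = res$aggregate, confusion = as.list(res$confusion),
    error_rates_per_min = rates,
    votes = res$votes,
    vote_accuracy = if (!is.null(res$votes))
      mean(res$votes$voted_label == res$votes$true_label) else NA_real_
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  summary
}
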