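# Plain-text persistence: one CSV per recording (time_ms + one column
# per channel, mV) with a JSON sidecar holding sampling rate, MVC
# trials, Borg reports, generator profile and processing stage; TSV
# writers for feature matrices and segment manifests; PNG export for
# scalogram images.

#' Write a recording to CSV + JSON sidecar
#'
#' @param recording a `semg_recording`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, recording$subject_id)
  df <- data.frame(time_ms = (seq_len(ncol(recording$signal)) - 1) /
                     recording$fs * 1000)
  for (ch in recording$channel_names) {
    df[[ch]] <- recording$signal[match(ch, recording$channel_names), ]
  }
  csv <- paste0(base, ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  meta <- list(subject_id = recording$subject_id, fs = recording$fs,
               channel_names = recording$channel_names,
               duration_s = recording$duration_s, stage = recording$stage,
               mvc_trials = recording$mvc_trials,
               borg_reports = recording$borg_reports)
  if (!is.null(recording$profile)) {
    meta$profile <- unclass(recording$profile)
  }
  if (!is.null(recording$mvc_reference)) {
    meta$mvc_reference <- as.list(recording$mvc_reference)
  }
  js <- paste0(base, ".json")
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}

#' Read a recording written by [write_recording()]
#'
#' @param csv_path path to the `.csv` file (the `.json` sidecar is
#'   expected next to it).
#' @return a `semg_recording`.
#' @export
read_recording <- function(csv_path) {
  js <- sub("\\.csv$", ".json", csv_path)
  check_that(file.exists(csv_path) && file.exists(js),
             "recording CSV or JSON sidecar not found")
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  df <- utils::read.csv(csv_path)
  chans <- meta$channel_names
  signal <- t(as.matrix(df[, chans, drop = FALSE]))
  dimnames(signal) <- list(chans, NULL)
  rec <- structure(list(subject_id = meta$subject_id, fs = meta$fs,
                        channel_names = chans, signal = signal,
                        mvc_trials = lapply(meta$mvc_trials, as.numeric),
                        borg_reports = as.data.frame(meta$borg_reports),
                        duration_s = meta$duration_s, stage = meta$stage),
                   class = "semg_recording")
  if (!is.null(meta$profile)) {
    rec$profile <- structure(meta$profile, class = "semg_subject_profile")
  }
  if (!is.null(meta$mvc_reference)) {
    rec$mvc_reference <- unlist(meta$mvc_reference)
  }
  rec
}

#' Write a labeled feature matrix as TSV
#'
#' One row per window: metadata columns (subject_id, start_ms,
#' task_progress, borg, class, label_source) followed by the 32 feature
#' columns.
#'
#' @param fm result of [feature_matrix()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_features <- function(fm, path) {
  df <- cbind(fm$meta, as.data.frame(fm$x))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a segment manifest as TSV
#'
#' @param dataset a labeled `semg_dataset`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_manifest <- function(dataset, path) {
  utils::write.table(dataset$index, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a scalogram image as PNG
#'
#' Requires the `png` package.
#'
#' @param image a `semg_scalogram_image`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_image_png <- function(image, path) {
  check_that(requireNamespace("png", quietly = TRUE),
             "the png package is required to write PNG files")
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}
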