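# Sliding-window segmentation, compound fatigue labeling, and
# leakage-safe leave-one-subject-out splitting.
#
# Labels combine two independent readings of fatigue: the temporal phase
# of the task (early / middle / late thirds) and the self-reported Borg
# score (0-2 / 3-5 / 6-10). When the two disagree the higher class wins -
# a safety-first rule for monitoring applications, which deliberately
# biases labels toward the fatigued classes.

#' The compound labeling rule
#'
#' @param progress_breaks inner break points of the three half-open
#'   task-progress bins `[0, b1] (b1, b2] (b2, 1]`.
#' @param borg_breaks highest Borg score of the first and second bin;
#'   default bins are `{0,1,2}`, `{3,4,5}`, `{6..10}`.
#' @return an object of class `semg_label_rule`.
#' @export
label_rule <- function(progress_breaks = c(1 / 3, 2 / 3),
                       borg_breaks = c(2, 5)) {
  check_that(length(progress_breaks) == 2 &&
               all(diff(c(0, progress_breaks, 1)) > 0),
             "progress_breaks must partition [0,1]")
  check_that(length(borg_breaks) == 2 && all(diff(c(-1, borg_breaks, 10)) > 0),
             "borg_breaks must partition 0..10")
  structure(list(progress_breaks = progress_breaks,
                 borg_breaks = borg_breaks,
                 classes = fatigue_classes("threeclass"),
                 disagreement_policy = "conservative_max"),
            class = "semg_label_rule")
}

#' Slide fixed-length windows over a recording
#'
#' Windows start at `0, hop_ms, 2*hop_ms, ...`; a recording shorter than
#' one window yields zero segments (with a warning). Each segment carries
#' the task-progress fraction of its midpoint and the Borg score of the
#' nearest preceding self-report (step-function interpolation: a report
#' describes the effort just performed).
#'
#' @param recording a `semg_recording` (raw or preprocessed).
#' @param window_ms window length in ms (2500 by default: 2500 samples at
#'   1000 Hz).
#' @param hop_ms hop in ms (one tenth of the window by default).
#' @param channels channels to segment (default: all).
#' @return a `semg_segments` object: list with `samples` (list of numeric
#'   windows) and a data.frame `index` (subject_id, channel, start_ms,
#'   task_progress, borg).
#' @export
slide_windows <- function(recording, window_ms = 2500, hop_ms = 250,
                          channels = NULL) {
  check_that(inherits(recording, "semg_recording"),
             "recording must be a semg_recording")
  check_that(hop_ms >= 1, "hop_ms must be >= 1")
  fs <- recording$fs
  wlen <- round(window_ms * fs / 1000)
  hop <- round(hop_ms * fs / 1000)
  n <- ncol(recording$signal)
  l_ms <- n / fs * 1000
  if (is.null(channels)) channels <- recording$channel_names
  if (n < wlen) {
    warning("recording shorter than one window; returning zero segments")
    starts <- integer(0)
  } else {
    starts <- seq(0, n - wlen, by = hop)   # in samples
  }
  borg_at <- function(t_ms) {
    br <- recording$borg_reports
    idx <- findInterval(t_ms / 1000, br$time_s)
    # before any report: no exertion has been declared yet
    ifelse(idx == 0, 0L, br$score[pmax(idx, 1)])
  }
  samples <- list()
  rows <- list()
  for (ch in channels) {
    ci <- match(ch, recording$channel_names)
    check_that(!is.na(ci), sprintf("unknown channel %s", ch))
    for (s0 in starts) {
      samples[[length(samples) + 1]] <-
        recording$signal[ci, (s0 + 1):(s0 + wlen)]
    }
    if (length(starts)) {
      start_ms <- starts / fs * 1000
      mid_ms <- start_ms + window_ms / 2
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = recording$subject_id, channel = ch,
        start_ms = start_ms,
        task_progress = pmin(mid_ms / l_ms, 1),
        borg = as.integer(borg_at(mid_ms)),
        stringsAsFactors = FALSE)
    }
  }
  index <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), channel = character(0),
               start_ms = numeric(0), task_progress = numeric(0),
               borg = integer(0))
  structure(list(samples = samples, index = index, fs = fs,
                 window_ms = window_ms, hop_ms = hop_ms),
            class = "semg_segments")
}

#' Assign a fatigue class to one window
#'
#' The phase class comes from the task-progress bin, the Borg class from
#' the self-report bin; the assigned class is the higher of the two
#' (conservative upgrade). `label_source` records whether the two readings
#' agreed (`"consensus"`) or the label was upgraded (`"upgraded"`).
#'
#' @param task_progress fraction in `[0, 1]` (vectorized).
#' @param borg integer score 0-10 (vectorized).
#' @param rule a [label_rule()].
#' @return data.frame with columns `class` (ordered factor) and
#'   `label_source`.
#' @export
assign_label <- function(task_progress, borg, rule = label_rule()) {
  check_that(all(task_progress >= 0 & task_progress <= 1),
             "task_progress must lie in [0, 1]")
  check_that(all(borg == round(borg) & borg >= 0 & borg <= 10),
             "borg must be an integer in 0..10")
  pb <- rule$progress_breaks
  bb <- rule$borg_breaks
  phase_cl <- 1L + (task_progress > pb[1]) + (task_progress > pb[2])
  borg_cl <- 1L + (borg > bb[1]) + (borg > bb[2])
  cl <- pmax(phase_cl, borg_cl)
  data.frame(
    class = factor(rule$classes[cl], levels = rule$classes, ordered = TRUE),
    label_source = ifelse(phase_cl == borg_cl, "consensus", "upgraded"),
    stringsAsFactors = FALSE)
}

#' Label every segment of a windowed recording
#'
#' @param segments a `semg_segments` from [slide_windows()].
#' @param rule a [label_rule()].
#' @param task `"threeclass"` or `"binary"` (see [binarize_labels()]).
#' @return a `semg_dataset`: `segments` plus parallel `labels` columns
#'   (`class`, `label_source`) bound into the index.
#' @export
label_segments <- function(segments, rule = label_rule(),
                           task = c("threeclass", "binary")) {
  task <- match.arg(task)
  lab <- assign_label(segments$index$task_progress, segments$index$borg, rule)
  segments$index$class <- lab$class
  segments$index$label_source <- lab$label_source
  segments$task <- "threeclass"
  class(segments) <- c("semg_dataset", class(segments))
  if (task == "binary") segments <- binarize_labels(segments)
  segments
}

#' Collapse three fatigue classes to the binary task
#'
#' `NoFatigue` stays; `ModerateFatigue` and `HardFatigue` map to
#' `Fatigue`. Idempotent.
#'
#' @param dataset a labeled `semg_dataset`.
#' @return the dataset with binary labels.
#' @export
binarize_labels <- function(dataset) {
  check_that(!is.null(dataset$index$class), "dataset must be labeled")
  cls <- as.character(dataset$index$class)
  bin <- ifelse(cls == "NoFatigue", "NoFatigue", "Fatigue")
  dataset$index$class <- factor(bin, levels = fatigue_classes("binary"),
                                ordered = TRUE)
  dataset$task <- "binary"
  dataset
}

#' Keep only consensus-labeled segments
#'
#' Drops every segment whose label was conservatively upgraded, preserving
#' order. Idempotent.
#'
#' @param dataset a labeled `semg_dataset`.
#' @return the filtered dataset.
#' @export
consensus_filter <- function(dataset) {
  check_that(!is.null(dataset$index$label_source),
             "dataset must carry label_source")
  keep <- dataset$index$label_source == "consensus"
  dataset$samples <- dataset$samples[keep]
  dataset$index <- dataset$index[keep, , drop = FALSE]
  rownames(dataset$index) <- NULL
  dataset
}

#' Leave-one-subject-out split
#'
#' @param subject_ids character vector of unique subject ids.
#' @return a `semg_loso_split`: list of folds, each with
#'   `train_subject_ids` and `test_subject_id`.
#' @export
loso_split <- function(subject_ids) {
  check_that(length(subject_ids) >= 2, "need at least 2 subjects")
  check_that(!anyDuplicated(subject_ids), "duplicate subject ids")
  folds <- lapply(subject_ids, function(s) {
    list(train_subject_ids = setdiff(subject_ids, s), test_subject_id = s)
  })
  structure(list(folds = folds, subject_ids = subject_ids),
            class = "semg_loso_split")
}

#' Assert subject-level disjointness of a fold
#'
#' Checked on segment provenance (the subject ids actually present in the
#' train and test sets), not just on the split table. A violation is a
#' hard error, never a warning.
#'
#' @param train_subjects subject ids present in training segments.
#' @param test_subjects subject ids present in test segments.
#' @param fold the fold definition being checked.
#' @return `TRUE` invisibly.
#' @export
assert_no_leakage <- function(train_subjects, test_subjects, fold) {
  train_subjects <- unique(train_subjects)
  test_subjects <- unique(test_subjects)
  if (length(intersect(train_subjects, test_subjects)) > 0 ||
      fold$test_subject_id %in% train_subjects ||
      !all(test_subjects %in% fold$test_subject_id)) {
    stop(structure(
      class = c("semg_leakage_error", "error", "condition"),
      list(message = paste0(
        "subject leakage detected in LOSO fold for test subject ",
        fold$test_subject_id), call = sys.call(-1))))
  }
  invisible(TRUE)
}
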