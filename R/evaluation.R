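# LOSO experiment driver and metrics: confusion matrices, accuracy,
# per-class precision / recall / F1 with macro averages, ROC and
# precision-recall curves with AUCs, and the full-vs-consensus labeling
# comparison.

#' Confusion matrix
#'
#' @param true_labels,predicted_labels parallel label vectors.
#' @param class_order ordered class labels.
#' @return a `semg_confusion`: integer matrix `counts` (rows = true,
#'   columns = predicted) with `class_order`.
#' @export
confusion <- function(true_labels, predicted_labels,
                      class_order = NULL) {
  tl <- as.character(true_labels)
  pl <- as.character(predicted_labels)
  check_that(length(tl) == length(pl), "label vectors differ in length")
  if (is.null(class_order)) class_order <- sort(unique(c(tl, pl)))
  check_that(all(c(tl, pl) %in% class_order),
             "label outside class_order")
  counts <- table(factor(tl, levels = class_order),
                  factor(pl, levels = class_order))
  counts <- matrix(as.integer(counts), nrow = length(class_order),
                   dimnames = list(true = class_order,
                                   predicted = class_order))
  structure(list(counts = counts, class_order = class_order),
            class = "semg_confusion")
}

#' Classification metrics from a confusion matrix
#'
#' Per-class (one-vs-rest) precision `TP/(TP+FP)`, recall `TP/(TP+FN)`
#' and F1 `2TP/(2TP+FP+FN)`, with unweighted macro averages. Headline
#' accuracy is trace/total; the one-vs-rest micro form that also counts
#' true negatives (which coincides with trace/total for two classes) is
#' reported as `accuracy_ovr`. Zero-denominator classes yield `NA` and
#' are excluded from macro averages (`n_undefined` counts them).
#'
#' @param cm a `semg_confusion`.
#' @return list of metrics.
#' @export
eval_metrics <- function(cm) {
  m <- cm$counts
  total <- sum(m)
  check_that(total > 0, "empty confusion matrix")
  nc <- nrow(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  list(accuracy = sum(tp) / total,
       accuracy_ovr = sum(tp + tn) / (nc * total),
       precision = precision, recall = recall, f1 = f1,
       macro_precision = mean(precision, na.rm = TRUE),
       macro_recall = mean(recall, na.rm = TRUE),
       macro_f1 = mean(f1, na.rm = TRUE),
       n_undefined = sum(is.na(precision) | is.na(recall) | is.na(f1)))
}

roc_curve_one <- function(score, truth) {
  # truth: logical (positive class); threshold swept over scores
  ord <- order(score, decreasing = TRUE)
  tr <- truth[ord]
  np <- sum(tr)
  nn <- sum(!tr)
  tpr <- c(0, cumsum(tr) / np)
  fpr <- c(0, cumsum(!tr) / nn)
  # collapse tied scores to their last point
  keep <- c(diff(score[ord]) != 0, TRUE)
  tpr <- c(0, (cumsum(tr) / np)[keep])
  fpr <- c(0, (cumsum(!tr) / nn)[keep])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

pr_curve_one <- function(score, truth) {
  ord <- order(score, decreasing = TRUE)
  tr <- truth[ord]
  np <- sum(tr)
  keep <- c(diff(score[ord]) != 0, TRUE)
  tp <- cumsum(tr)[keep]
  pp <- seq_along(tr)[keep]
  precision <- tp / pp
  recall <- tp / np
  # step interpolation (average precision)
  auc <- sum(diff(c(0, recall)) * precision)
  list(recall = c(0, recall), precision = c(1, precision), auc = auc)
}

#' ROC and precision-recall curves with AUCs
#'
#' One-vs-rest per class. ROC AUC uses the trapezoid rule; PR AUC uses
#' step interpolation (average precision).
#'
#' @param scores probability matrix (columns named by class).
#' @param true_labels parallel truth labels.
#' @return named list per class with `roc`, `pr`, `roc_auc`, `pr_auc`.
#' @export
roc_pr <- function(scores, true_labels) {
  scores <- as.matrix(scores)
  classes <- colnames(scores)
  check_that(!is.null(classes), "scores must have class column names")
  tl <- as.character(true_labels)
  check_that(length(unique(tl)) >= 2,
             "single-class truth: AUC undefined")
  out <- list()
  for (cl in classes) {
    truth <- tl == cl
    if (!any(truth) || all(truth)) {
      out[[cl]] <- list(roc = NULL, pr = NULL, roc_auc = NA_real_,
                        pr_auc = NA_real_)
      next
    }
    roc <- roc_curve_one(scores[, cl], truth)
    pr <- pr_curve_one(scores[, cl], truth)
    out[[cl]] <- list(roc = roc[c("fpr", "tpr")], pr = pr[c("recall",
                                                            "precision")],
                      roc_auc = roc$auc, pr_auc = pr$auc)
  }
  out
}

#' LOSO pipeline configuration
#'
#' @param window_ms,hop_ms windowing parameters.
#' @param task `"binary"` or `"threeclass"`.
#' @param rule a [label_rule()].
#' @param consensus_only drop conservatively upgraded segments from both
#'   train and test sets.
#' @param features a [feature_config()] (baseline models).
#' @param cwt a [cwt_config()] (image model).
#' @param image_size rendered image side in pixels (image model); must be
#'   divisible by 8 for the scratch backbone.
#' @param channels channels to use (default: all four).
#' @param seed training seed.
#' @return list of class `semg_loso_config`.
#' @export
loso_config <- function(window_ms = 2500, hop_ms = 250,
                        task = c("binary", "threeclass"),
                        rule = label_rule(), consensus_only = FALSE,
                        features = feature_config(),
                        cwt = cwt_config(), image_size = 224L,
                        channels = NULL, seed = 1L) {
  task <- match.arg(task)
  structure(list(window_ms = window_ms, hop_ms = hop_ms, task = task,
                 rule = rule, consensus_only = isTRUE(consensus_only),
                 features = features, cwt = cwt,
                 image_size = as.integer(image_size), channels = channels,
                 seed = as.integer(seed)),
            class = "semg_loso_config")
}

# preprocess + window + label one recording; representation depends on the
# model family. Windowing is strictly per subject, so per-subject results
# are identical whether computed before or after the subject split; the
# split's leakage guarantee is enforced on segment provenance every fold.
subject_representation <- function(recording, config, kind) {
  pr <- if (identical(recording$stage, "raw")) preprocess_recording(recording)
        else recording
  seg <- slide_windows(pr, config$window_ms, config$hop_ms,
                       channels = config$channels)
  ds <- label_segments(seg, config$rule, task = "threeclass")
  if (config$task == "binary") ds <- binarize_labels(ds)
  if (kind == "features") {
    fm <- feature_matrix(ds, config$features)
    list(x = fm$x, meta = fm$meta, n_dropped = fm$n_dropped)
  } else {
    imgs <- lapply(ds$samples, function(w) {
      render_image(cwt_morlet(w, ds$fs, config$cwt),
                   config$image_size, config$image_size)
    })
    list(images = imgs, meta = ds$index)
  }
}

filter_consensus_rows <- function(rep_obj) {
  keep <- rep_obj$meta$label_source == "consensus"
  rep_obj$meta <- rep_obj$meta[keep, , drop = FALSE]
  if (!is.null(rep_obj$x)) rep_obj$x <- rep_obj$x[keep, , drop = FALSE]
  if (!is.null(rep_obj$images)) rep_obj$images <- rep_obj$images[keep]
  rep_obj
}

#' Run a leave-one-subject-out experiment
#'
#' For every fold: hold out one subject, train on the remaining
#' subjects' windows, evaluate on the held-out subject's windows. The
#' subject-disjointness of train and test segments is asserted on
#' segment provenance in every fold; a violation is a hard error.
#'
#' @param cohort list of `semg_recording` (>= 2 subjects).
#' @param config a [loso_config()].
#' @param model_spec a [baseline_spec()] (feature models) or a
#'   [train_spec()] (image model).
#' @return a `semg_eval_report`: per-fold metrics, aggregate
#'   mean +/- standard deviation, summed confusion matrix, pooled
#'   per-class ROC/PR AUCs, and the run configuration.
#' @export
run_loso <- function(cohort, config = loso_config(), model_spec) {
  check_that(length(cohort) >= 2, "cohort must have >= 2 subjects")
  ids <- vapply(cohort, function(r) r$subject_id, character(1))
  split <- loso_split(ids)
  kind <- if (inherits(model_spec, "semg_train_spec")) "images" else "features"
  reps <- lapply(cohort, subject_representation, config = config,
                 kind = kind)
  names(reps) <- ids
  if (config$consensus_only) {
    reps <- lapply(reps, filter_consensus_rows)
    for (id in ids) {
      check_that(nrow(reps[[id]]$meta) > 0,
                 sprintf("consensus subset empty for subject %s", id))
    }
  }
  classes <- fatigue_classes(if (config$task == "binary") "binary"
                             else "threeclass")
  fold_rows <- list()
  cm_total <- NULL
  pooled_prob <- list()
  pooled_true <- list()
  per_fold <- list()
  for (fi in seq_along(split$folds)) {
    fold <- split$folds[[fi]]
    tr <- reps[fold$train_subject_ids]
    te <- reps[[fold$test_subject_id]]
    tr_meta <- do.call(rbind, lapply(tr, `[[`, "meta"))
    assert_no_leakage(tr_meta$subject_id, te$meta$subject_id, fold)
    y_tr <- factor(as.character(tr_meta$class), levels = classes,
                   ordered = TRUE)
    y_te <- factor(as.character(te$meta$class), levels = classes,
                   ordered = TRUE)
    if (kind == "features") {
      x_tr <- do.call(rbind, lapply(tr, `[[`, "x"))
      model <- train_baseline(x_tr, y_tr, model_spec, seed = config$seed)
      pred <- predict(model, te$x)
    } else {
      imgs_tr <- do.call(c, lapply(tr, `[[`, "images"))
      model <- train_image_model(imgs_tr, y_tr, model_spec)
      pred <- predict(model, te$images)
    }
    cm <- confusion(y_te, pred$class, classes)
    mt <- eval_metrics(cm)
    cm_total <- if (is.null(cm_total)) cm$counts else cm_total + cm$counts
    fold_rows[[fi]] <- data.frame(
      fold = fi, test_subject = fold$test_subject_id,
      n_test = length(y_te), accuracy = mt$accuracy,
      accuracy_ovr = mt$accuracy_ovr,
      precision = mt$macro_precision, recall = mt$macro_recall,
      f1 = mt$macro_f1, stringsAsFactors = FALSE)
    pooled_prob[[fi]] <- pred$prob
    pooled_true[[fi]] <- as.character(y_te)
    per_fold[[fi]] <- list(confusion = cm, metrics = mt)
  }
  folds_df <- do.call(rbind, fold_rows)
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  aggregate <- sapply(folds_df[, c("accuracy", "accuracy_ovr", "precision",
                                   "recall", "f1")], agg)
  prob_all <- do.call(rbind, pooled_prob)
  true_all <- unlist(pooled_true)
  curves <- tryCatch(roc_pr(prob_all, true_all), error = function(e) NULL)
  structure(list(task = config$task, classes = classes, folds = folds_df,
                 aggregate = aggregate,
                 confusion = structure(list(counts = cm_total,
                                            class_order = classes),
                                       class = "semg_confusion"),
                 curves = curves, per_fold = per_fold,
                 n_segments = sum(folds_df$n_test),
                 averaging = "macro", config = config,
                 model_spec = model_spec),
            class = "semg_eval_report")
}

#' Compare full-label and consensus-only evaluation
#'
#' Runs the same LOSO experiment twice with identical folds and seeds,
#' once on all segments and once restricted (train and test) to
#' consensus-labeled segments.
#'
#' @inheritParams run_loso
#' @return list with elements `full` and `consensus` (two
#'   `semg_eval_report`s) and `n_removed`, the count of upgraded
#'   segments excluded from the consensus run.
#' @export
compare_full_vs_consensus <- function(cohort, config = loso_config(),
                                      model_spec) {
  cfg_full <- config
  cfg_full$consensus_only <- FALSE
  cfg_cons <- config
  cfg_cons$consensus_only <- TRUE
  full <- run_loso(cohort, cfg_full, model_spec)
  cons <- run_loso(cohort, cfg_cons, model_spec)
  list(full = full, consensus = cons,
       n_removed = full$n_segments - cons$n_segments)
}

#' @export
print.semg_eval_report <- function(x, ...) {
  cat(sprintf("LOSO evaluation (%s task, %d folds, %d segments)\n",
              x$task, nrow(x$folds), x$n_segments))
  ag <- x$aggregate
  for (m in colnames(ag)) {
    cat(sprintf("  %-13s %.4f (+/- %.4f)\n", m, ag["mean", m], ag["sd", m]))
  }
  cat("confusion (rows = true):\n")
  print(x$confusion$counts)
  invisible(x)
}
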