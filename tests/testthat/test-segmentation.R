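test_that("sliding windows follow the count formula and progress rule", {
  rec <- make_recording(10000, n_channels = 1)
  seg <- slide_windows(rec, 2500, 250)
  expect_equal(nrow(seg$index), 31)      # floor((10000-2500)/250)+1
  expect_equal(seg$index$start_ms, seq(0, 7500, by = 250))
  expect_length(seg$samples[[1]], 2500)
  one <- slide_windows(make_recording(2500, n_channels = 1), 2500, 250)
  expect_equal(nrow(one$index), 1)
  expect_equal(one$index$task_progress, 0.5)
  expect_warning(
    none <- slide_windows(make_recording(2499, n_channels = 1), 2500, 250),
    "shorter")
  expect_equal(nrow(none$index), 0)
})

test_that("window counts match brute-force enumeration on random cases", {
  set.seed(12)
  for (i in 1:200) {
    l <- sample(100:4000, 1)
    w <- sample(50:1500, 1)
    h <- sample(10:500, 1)
    starts <- oracle_window_starts(l, w, h)
    n_expected <- length(starts)
    formula_n <- if (l < w) 0 else floor((l - w) / h) + 1
    expect_equal(formula_n, n_expected)
    if (i <= 25) {   # cross-check against the implementation on a subset
      rec <- make_recording(l, n_channels = 1)
      seg <- suppressWarnings(slide_windows(rec, w, h))
      expect_equal(nrow(seg$index), n_expected)
      if (n_expected > 0) expect_equal(seg$index$start_ms, starts)
    }
  }
})

test_that("windows take the nearest preceding Borg report", {
  borg <- data.frame(time_s = c(2, 4, 6), score = c(1L, 4L, 7L))
  rec <- make_recording(8000, n_channels = 1, borg = borg)
  seg <- slide_windows(rec, 1000, 1000)
  # midpoints at 0.5, 1.5, ..., 7.5 s
  expect_equal(seg$index$borg, c(0L, 0L, 1L, 1L, 4L, 4L, 7L, 7L))
})

test_that("the compound rule reproduces the consensus table and upgrades", {
  cells <- expand.grid(progress = c(0.1, 0.5, 0.9), borg = c(1L, 4L, 8L))
  expected <- matrix(c("NoFatigue", "ModerateFatigue", "HardFatigue",
                       "ModerateFatigue", "ModerateFatigue", "HardFatigue",
                       "HardFatigue", "HardFatigue", "HardFatigue"),
                     3, byrow = TRUE)   # rows = borg bin, cols = phase bin
  for (r in seq_len(nrow(cells))) {
    lab <- assign_label(cells$progress[r], cells$borg[r])
    pi <- match(cells$progress[r], c(0.1, 0.5, 0.9))
    bi <- match(cells$borg[r], c(1L, 4L, 8L))
    expect_identical(as.character(lab$class), expected[bi, pi])
    expect_identical(lab$label_source,
                     if (pi == bi) "consensus" else "upgraded")
  }
  # named examples
  l1 <- assign_label(0.20, 1L)
  expect_identical(as.character(l1$class), "NoFatigue")
  expect_identical(l1$label_source, "consensus")
  l2 <- assign_label(0.20, 4L)
  expect_identical(as.character(l2$class), "ModerateFatigue")
  expect_identical(l2$label_source, "upgraded")
  l3 <- assign_label(0.90, 9L)
  expect_identical(as.character(l3$class), "HardFatigue")
  expect_identical(l3$label_source, "consensus")
  expect_error(assign_label(0.5, 11L), class = "semg_validation_error")
  expect_error(assign_label(1.2, 3L), class = "semg_validation_error")
})

test_that("assign_label is monotone in progress and in borg", {
  grid <- seq(0, 1, length.out = 101)
  for (b in c(0L, 3L, 6L, 10L)) {
    cl <- as.integer(assign_label(grid, rep(b, 101))$class)
    expect_true(all(diff(cl) >= 0))
  }
  for (p in c(0, 0.4, 0.8)) {
    cl <- as.integer(assign_label(rep(p, 11), 0:10)$class)
    expect_true(all(diff(cl) >= 0))
  }
})

test_that("consensus_filter removes exactly the upgraded segments", {
  borg <- data.frame(time_s = c(0, 3), score = c(0L, 5L))
  rec <- make_recording(12000, n_channels = 1, borg = borg)
  ds <- label_segments(slide_windows(rec, 1000, 1000))
  n_up <- sum(ds$index$label_source == "upgraded")
  expect_gt(n_up, 0)
  cf <- consensus_filter(ds)
  expect_equal(nrow(cf$index), nrow(ds$index) - n_up)
  expect_true(all(cf$index$label_source == "consensus"))
  # no disagreement survives, and the filter is idempotent
  rl <- label_rule()
  pcl <- 1L + (cf$index$task_progress > 1 / 3) +
    (cf$index$task_progress > 2 / 3)
  bcl <- 1L + (cf$index$borg > 2) + (cf$index$borg > 5)
  expect_true(all(pcl == bcl))
  expect_identical(consensus_filter(cf)$index, cf$index)
  # zero-upgrade dataset is returned unchanged
  ds_cons <- ds
  keep <- ds$index$label_source == "consensus"
  ds_cons$samples <- ds$samples[keep]
  ds_cons$index <- ds$index[keep, ]
  rownames(ds_cons$index) <- NULL
  expect_identical(consensus_filter(ds_cons)$index, ds_cons$index)
})

test_that("binarize_labels maps classes and conserves counts", {
  borg <- data.frame(time_s = c(0, 3), score = c(0L, 5L))
  rec <- make_recording(12000, n_channels = 1, borg = borg)
  ds <- label_segments(slide_windows(rec, 1000, 1000))
  n_mod <- sum(ds$index$class == "ModerateFatigue")
  n_hard <- sum(ds$index$class == "HardFatigue")
  bn <- binarize_labels(ds)
  expect_identical(levels(bn$index$class), c("NoFatigue", "Fatigue"))
  expect_equal(sum(bn$index$class == "Fatigue"), n_mod + n_hard)
  expect_identical(binarize_labels(bn)$index, bn$index)
})

test_that("LOSO split is a clean partition", {
  ids <- sprintf("S%02d", 1:20)
  sp <- loso_split(ids)
  expect_length(sp$folds, 20)
  expect_setequal(vapply(sp$folds, `[[`, character(1), "test_subject_id"),
                  ids)
  for (f in sp$folds) {
    expect_length(intersect(f$train_subject_ids, f$test_subject_id), 0)
    expect_setequal(c(f$train_subject_ids, f$test_subject_id), ids)
  }
  sp2 <- loso_split(c("a", "b"))
  expect_length(sp2$folds, 2)
  expect_length(sp2$folds[[1]]$train_subject_ids, 1)
  expect_error(loso_split(c("a", "a", "b")),
               class = "semg_validation_error")
  expect_error(loso_split("a"), class = "semg_validation_error")
})

test_that("leakage assertions fire on corrupted provenance", {
  fold <- list(train_subject_ids = c("S1", "S2"), test_subject_id = "S3")
  expect_true(assert_no_leakage(c("S1", "S2"), "S3", fold))
  expect_error(assert_no_leakage(c("S1", "S2", "S3"), "S3", fold),
               class = "semg_leakage_error")
  expect_error(assert_no_leakage(c("S1", "S2"), c("S2", "S3"), fold),
               class = "semg_leakage_error")
})
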