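test_that("confusion matrices tally correctly", {
  cm <- confusion(c("a", "b", "a"), c("a", "b", "a"), c("a", "b"))
  expect_equal(unname(cm$counts), matrix(c(2L, 0L, 0L, 1L), 2))
  cm2 <- confusion(c(0, 0, 1, 1), c(0, 1, 1, 1), c("0", "1"))
  expect_equal(unname(cm2$counts), matrix(c(1L, 0L, 1L, 2L), 2))
  set.seed(23)
  tl <- sample(letters[1:3], 1000, TRUE)
  pl <- sample(letters[1:3], 1000, TRUE)
  cm3 <- confusion(tl, pl, letters[1:3])
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cm3$counts[i, j],
                 sum(tl == letters[i] & pl == letters[j]))
  }
  expect_equal(sum(cm3$counts), 1000)
  expect_error(confusion(c("a", "z"), c("a", "a"), c("a", "b")),
               class = "semg_validation_error")
})

test_that("metrics reproduce hand-computed values", {
  perfect <- confusion(rep(c("a", "b"), 5), rep(c("a", "b"), 5),
                       c("a", "b"))
  mp <- eval_metrics(perfect)
  expect_equal(mp$accuracy, 1)
  expect_equal(unname(mp$f1), c(1, 1))
  toy <- structure(list(counts = matrix(c(45L, 10L, 5L, 40L), 2,
                                        dimnames = list(c("n", "p"),
                                                        c("n", "p"))),
                        class_order = c("n", "p")),
                   class = "semg_confusion")
  mt <- eval_metrics(toy)
  expect_equal(mt$accuracy, 0.85)
  expect_equal(unname(mt$precision[1]), 45 / 55, tolerance = 1e-12)
  expect_equal(unname(mt$recall[1]), 0.9)
  expect_equal(unname(mt$f1[1]), 2 * 45 / (2 * 45 + 5 + 10),
               tolerance = 1e-12)
  # for two classes the one-vs-rest micro accuracy equals trace/total
  expect_equal(mt$accuracy_ovr, mt$accuracy)
})

test_that("F1 is the harmonic mean of precision and recall", {
  set.seed(24)
  for (i in 1:100) {
    nc <- sample(2:4, 1)
    m <- matrix(rpois(nc * nc, 20) + 1L, nc)
    cm <- structure(list(counts = m, class_order = letters[1:nc]),
                    class = "semg_confusion")
    mt <- eval_metrics(cm)
    hm <- 2 * mt$precision * mt$recall / (mt$precision + mt$recall)
    expect_equal(unname(mt$f1), unname(hm), tolerance = 1e-12)
    if (nc == 2) expect_equal(mt$accuracy_ovr, mt$accuracy)
    expect_gte(mt$macro_f1, min(mt$f1))
    expect_lte(mt$macro_f1, max(mt$f1))
  }
})

test_that("undefined per-class metrics surface as NA with a count", {
  m <- matrix(c(5L, 0L, 0L, 0L), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  mt <- eval_metrics(structure(list(counts = m,
                                    class_order = c("a", "b")),
                               class = "semg_confusion"))
  expect_true(is.na(mt$precision[2]))
  expect_gte(mt$n_undefined, 1)
  expect_equal(mt$macro_recall, 1)  # NA-excluded mean
})

test_that("ROC and PR curves behave at the extremes and under the null", {
  # perfectly separating scores
  sc <- cbind(a = c(0.9, 0.8, 0.2, 0.1), b = c(0.1, 0.2, 0.8, 0.9))
  rp <- roc_pr(sc, c("a", "a", "b", "b"))
  expect_equal(rp$a$roc_auc, 1)
  expect_equal(rp$b$pr_auc, 1)
  # ROC curve is monotone non-decreasing in both coordinates
  expect_true(all(diff(rp$a$roc$fpr) >= 0))
  expect_true(all(diff(rp$a$roc$tpr) >= 0))
  # independent scores give AUC 0.5 +/- 0.02 at n = 10000
  set.seed(25)
  n <- 10000
  s <- runif(n)
  lab <- sample(c("x", "y"), n, TRUE)
  rp0 <- roc_pr(cbind(x = s, y = 1 - s), lab)
  expect_lt(abs(rp0$x$roc_auc - 0.5), 0.02)
  expect_error(roc_pr(cbind(x = s, y = 1 - s), rep("x", n)),
               class = "semg_validation_error")
})

test_that("run_loso produces one fold per subject with honest aggregates", {
  cohort <- cached_cohort(3, duration_s = 25, seed = 31)
  cfg <- loso_config(task = "binary", hop_ms = 2500, seed = 31)
  rep <- run_loso(cohort, cfg, baseline_spec("random_forest", "binary"))
  expect_s3_class(rep, "semg_eval_report")
  expect_equal(nrow(rep$folds), 3)
  expect_equal(unname(rep$aggregate["mean", "accuracy"]),
               mean(rep$folds$accuracy))
  expect_equal(sum(rep$confusion$counts), sum(rep$folds$n_test))
  expect_true(all(rep$folds$accuracy >= 0 & rep$folds$accuracy <= 1))
})

test_that("full vs consensus comparison shares folds and drops upgrades", {
  cohort <- cached_cohort(3, duration_s = 25, seed = 31)
  cfg <- loso_config(task = "binary", hop_ms = 2500, seed = 31)
  cmp <- compare_full_vs_consensus(cohort, cfg,
                                   baseline_spec("decision_tree", "binary"))
  expect_identical(cmp$full$folds$test_subject,
                   cmp$consensus$folds$test_subject)
  expect_gte(cmp$n_removed, 0)
  expect_equal(cmp$full$n_segments - cmp$consensus$n_segments,
               cmp$n_removed)
})

test_that("a recording with phase-aligned reports yields identical reports", {
  # Borg reports engineered so every window is consensus-labeled: the
  # consensus run must then equal the full run exactly
  mk <- function(id, seed) {
    set.seed(seed)
    dur <- 24
    rec <- make_recording(dur * 1000, n_channels = 1, subject_id = id)
    rec$borg_reports <- data.frame(time_s = c(0, dur / 3, 2 * dur / 3),
                                   score = c(0L, 4L, 7L))
    rec
  }
  cohort <- list(mk("A", 1), mk("B", 2), mk("C", 3))
  cfg <- loso_config(task = "binary", window_ms = 2000, hop_ms = 2000,
                     seed = 5)
  cmp <- compare_full_vs_consensus(cohort, cfg,
                                   baseline_spec("decision_tree", "binary"))
  expect_equal(cmp$n_removed, 0)
  expect_equal(cmp$full$folds, cmp$consensus$folds)
  expect_equal(cmp$full$confusion$counts, cmp$consensus$confusion$counts)
})

test_that("corrupting fold provenance trips the hard leakage error", {
  fold <- list(train_subject_ids = c("S01", "S02"), test_subject_id = "S03")
  expect_error(assert_no_leakage(c("S01", "S02", "S03"), "S03", fold),
               class = "semg_leakage_error")
})
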