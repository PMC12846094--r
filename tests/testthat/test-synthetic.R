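test_that("profile validation rejects impossible physiology", {
  expect_error(subject_profile(duration_s = 0),
               class = "semg_validation_error")
  expect_error(subject_profile(mnf_start = 500, mnf_end = 480),
               class = "semg_validation_error")
  expect_error(subject_profile(mnf_start = 100, mnf_end = 15),
               class = "semg_validation_error")
  expect_error(subject_profile(mnf_start = 70, mnf_end = 120),
               class = "semg_validation_error")
  expect_error(borg_trajectory(1.5), class = "semg_validation_error")
})

test_that("zero-amplitude profiles yield all-zero signals of full shape", {
  p <- subject_profile(baseline_rms = 0, noise_floor = 0, duration_s = 3,
                       seed = 2)
  rec <- simulate_subject(p)
  expect_equal(dim(rec$signal), c(4L, 3000L))
  expect_true(all(rec$signal == 0))
})

test_that("simulation is bit-identical for a fixed profile and seed", {
  p <- subject_profile(duration_s = 4, seed = 42)
  r1 <- simulate_subject(p)
  r2 <- simulate_subject(p)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$mvc_trials, r2$mvc_trials)
  expect_identical(r1$borg_reports, r2$borg_reports)
})

test_that("recordings satisfy their structural invariants", {
  rec <- simulate_subject(subject_profile(duration_s = 12, seed = 3))
  expect_equal(nrow(rec$signal), length(rec$channel_names))
  expect_true(all(is.finite(rec$signal)))
  expect_true(all(vapply(rec$mvc_trials, length, integer(1)) == 3))
  expect_true(all(vapply(rec$mvc_trials, function(v) all(v > 0),
                         logical(1))))
  expect_true(all(rec$borg_reports$score >= 0 &
                    rec$borg_reports$score <= 10))
  expect_equal(rec$fs, 1000)
})

test_that("borg trajectories start low, end high, and never decrease", {
  p <- subject_profile()
  expect_lte(borg_trajectory(0, p), 2)
  expect_gte(borg_trajectory(1, p), 6)
  grid <- seq(0, 1, length.out = 101)
  for (shape in c(0.6, 1, 1.7)) {
    ps <- subject_profile(borg_shape = shape)
    expect_true(all(diff(borg_trajectory(grid, ps)) >= 0))
  }
})

test_that("the spectral schedule is recovered by the features module", {
  p <- subject_profile(mnf_start = 120, mnf_end = 70, duration_s = 20,
                       seed = 4)
  rec <- simulate_subject(p)
  pr <- preprocess_recording(rec)
  seg <- slide_windows(pr, 2500, 2500, channels = "BB")
  mdf_first <- spec_mdf(power_spectrum(seg$samples[[1]], rec$fs))
  mdf_last <- spec_mdf(power_spectrum(
    seg$samples[[length(seg$samples)]], rec$fs))
  expect_lt(mdf_last, mdf_first)
})

test_that("windowed MDF drifts down for every channel across a cohort", {
  cohort <- cached_cohort(20, duration_s = 20, seed = 19)
  for (rec in cohort) {
    pr <- preprocess_recording(rec)
    for (ch in pr$channel_names) {
      seg <- slide_windows(pr, 2500, 2500, channels = ch)
      mdf <- vapply(seg$samples,
                    function(w) spec_mdf(power_spectrum(w, pr$fs)),
                    numeric(1))
      rho <- cor(seq_along(mdf), mdf, method = "spearman")
      expect_lt(rho, 0)
    }
  }
})

test_that("the amplitude schedule reaches the configured end gain", {
  p <- subject_profile(rms_gain_end = 2, duration_s = 30, noise_floor = 0,
                       seed = 6)
  rec <- simulate_subject(p)
  x <- rec$signal[1, ]
  w <- 2500
  rms_start <- sqrt(mean(x[1:w]^2))
  rms_end <- sqrt(mean(x[(length(x) - w + 1):length(x)]^2))
  ratio <- rms_end / rms_start
  expect_gt(ratio, 2 * 0.75)
  expect_lt(ratio, 2 * 1.25)
})

test_that("cohorts have unique subjects and seed-dependent content", {
  cohort <- cached_cohort(20, duration_s = 20, seed = 19)
  ids <- vapply(cohort, function(r) r$subject_id, character(1))
  expect_length(unique(ids), 20)
  solo <- simulate_cohort(1, subject_profile(duration_s = 3, seed = 1),
                          seed = 5)
  expect_length(solo, 1)
  expect_equal(solo[[1]]$duration_s, 3)
  a <- simulate_cohort(2, subject_profile(duration_s = 3), seed = 1)
  b <- simulate_cohort(2, subject_profile(duration_s = 3), seed = 2)
  expect_false(identical(a[[1]]$signal, b[[1]]$signal))
  # reproducibility of the whole cohort under the master seed
  a2 <- simulate_cohort(2, subject_profile(duration_s = 3), seed = 1)
  expect_identical(a[[2]]$signal, a2[[2]]$signal)
  expect_error(simulate_cohort(0), class = "semg_validation_error")
})

test_that("recordings round-trip through the CSV + JSON dialect", {
  dir <- withr::local_tempdir()
  rec <- simulate_subject(subject_profile(duration_s = 2, seed = 8))
  write_recording(rec, dir)
  back <- read_recording(file.path(dir, paste0(rec$subject_id, ".csv")))
  expect_equal(back$signal, rec$signal, tolerance = 1e-12)
  expect_identical(back$channel_names, rec$channel_names)
  expect_equal(back$mvc_trials, rec$mvc_trials, tolerance = 1e-12)
  expect_equal(back$borg_reports$score, rec$borg_reports$score)
  expect_equal(back$fs, rec$fs)
  expect_identical(back$stage, "raw")
})
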