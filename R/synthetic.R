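# Synthetic sEMG cohort generator.
#
# The generator produces band-limited Gaussian noise whose short-time
# spectrum is a Gaussian bump in the 20-450 Hz surface-EMG band. Two
# schedules drive the fatigue signature the downstream pipeline assumes:
# the bump center glides from mnf_start down to mnf_end (spectral
# compression towards low frequencies), and a slowly varying amplitude
# envelope scales windowed RMS from baseline_rms up to
# baseline_rms * rms_gain_end, modulated by repetition bursts at the curl
# cadence. This reproduces the statistical structure of fatiguing dynamic
# contractions without claiming motor-unit-level realism.

#' Describe one synthetic subject
#'
#' @param subject_id character id.
#' @param baseline_rms target windowed RMS at task start, mV.
#' @param rms_gain_end multiplier of baseline RMS reached at task end
#'   (> 1 for a fatiguing subject).
#' @param mnf_start,mnf_end mean-frequency schedule endpoints in Hz;
#'   `mnf_end < mnf_start` for a fatiguing subject. Both must lie inside
#'   the 20-450 Hz sEMG band.
#' @param duration_s session length in seconds (the study's sessions ran
#'   roughly 4-5 minutes; the default is 270 s).
#' @param rep_period_s repetition (curl) period in seconds.
#' @param borg_every_reps a Borg 0-10 self-report is attached every this
#'   many repetitions (protocol: every three repetitions).
#' @param borg_start,borg_end Borg scores at task start/end before
#'   rounding; the trajectory is monotone between them.
#' @param borg_shape exponent of the Borg progress curve (1 = linear).
#' @param noise_floor additive wide-band instrumentation noise RMS, mV.
#' @param mvc_gain ratio of maximal-effort RMS to baseline RMS, used to
#'   synthesize the three MVC calibration trials.
#' @param seed integer substream seed for this subject.
#' @return an object of class `semg_subject_profile`.
#' @export
subject_profile <- function(subject_id = "S01",
                            baseline_rms = 0.05,
                            rms_gain_end = 2,
                            mnf_start = 120,
                            mnf_end = 70,
                            duration_s = 270,
                            rep_period_s = 3,
                            borg_every_reps = 3,
                            borg_start = 0,
                            borg_end = 9,
                            borg_shape = 1,
                            noise_floor = 0.002,
                            mvc_gain = 3,
                            seed = 1L) {
  check_that(duration_s > 0, "duration_s must be positive")
  check_that(baseline_rms >= 0, "baseline_rms must be non-negative")
  check_that(mnf_end <= mnf_start, "mnf_end must be <= mnf_start")
  check_that(mnf_end > 20 && mnf_start < 450,
             "mnf schedule must lie inside the 20-450 Hz band")
  check_that(borg_start >= 0 && borg_end <= 10 && borg_shape > 0,
             "borg trajectory parameters out of range")
  structure(list(subject_id = subject_id, baseline_rms = baseline_rms,
                 rms_gain_end = rms_gain_end, mnf_start = mnf_start,
                 mnf_end = mnf_end, duration_s = duration_s,
                 rep_period_s = rep_period_s,
                 borg_every_reps = borg_every_reps,
                 borg_start = borg_start, borg_end = borg_end,
                 borg_shape = borg_shape, noise_floor = noise_floor,
                 mvc_gain = mvc_gain, seed = as.integer(seed)),
            class = "semg_subject_profile")
}

semg_channels <- c("BB", "BRA", "TRI", "DEL")

#' Borg self-report trajectory
#'
#' Monotone non-decreasing, integer-valued rating of perceived exertion as
#' a function of task progress. A fatiguing default profile starts at
#' score <= 2 and ends at score >= 6.
#'
#' @param progress fraction of the task completed, in `[0, 1]` (vectorized).
#' @param profile a [subject_profile()].
#' @return integer score(s) in 0-10.
#' @export
borg_trajectory <- function(progress, profile = subject_profile()) {
  check_that(all(progress >= 0 & progress <= 1),
             "progress must lie in [0, 1]")
  raw <- profile$borg_start +
    (profile$borg_end - profile$borg_start) * progress^profile$borg_shape
  as.integer(pmin(10, pmax(0, round(raw))))
}

# stationary unit-variance noise with a Gaussian spectral bump at fc,
# truncated to the 20-450 Hz band; synthesized chunk-wise in the frequency
# domain and blended with a sqrt-Hann overlap-add
shaped_noise <- function(n, fs, fc_of_t, sigma_hz = 35) {
  chunk <- as.integer(fs)          # 1 s synthesis chunks
  hop <- chunk %/% 2
  win <- sqrt(0.5 - 0.5 * cos(2 * pi * seq(0, chunk - 1) / chunk))
  # sqrt-Hann at 50% overlap sums (in power) to a constant
  out <- numeric(n + 2 * chunk)
  freqs <- (seq_len(chunk) - 1) * fs / chunk
  fmir <- pmin(freqs, fs - freqs)  # two-sided frequency axis
  starts <- seq(1, n + chunk, by = hop)
  for (s0 in starts) {
    mid <- min(max(s0 + hop, 1), n)
    fc <- fc_of_t[mid]
    amp <- exp(-(fmir - fc)^2 / (2 * sigma_hz^2))
    amp[fmir < 20 | fmir > 450] <- 0
    wn <- stats::rnorm(chunk)
    shaped <- Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / chunk
    sdv <- stats::sd(shaped)
    if (sdv > 0) shaped <- shaped / sdv
    idx <- s0:(s0 + chunk - 1)
    out[idx] <- out[idx] + shaped * win
  }
  out[seq_len(n)] / sqrt(sum(win[seq(1, chunk, by = hop)]^2))
}

# repetition burst modulation with unit mean square, so it perturbs but
# does not bias the RMS schedule
rep_modulation <- function(n, fs, rep_period_s, depth = 0.5) {
  t <- seq_len(n) / fs
  m <- 1 + depth * sin(2 * pi * t / rep_period_s)
  m / sqrt(mean(m^2))
}

simulate_trace <- function(n, fs, profile) {
  progress <- seq_len(n) / n
  fc <- profile$mnf_start + (profile$mnf_end - profile$mnf_start) * progress
  base <- shaped_noise(n, fs, fc)
  target_rms <- profile$baseline_rms *
    (1 + (profile$rms_gain_end - 1) * progress)
  x <- base * target_rms * rep_modulation(n, fs, profile$rep_period_s)
  if (profile$noise_floor > 0) {
    x <- x + stats::rnorm(n, sd = profile$noise_floor)
  }
  x
}

#' Simulate one subject's recording session
#'
#' Generates a 4-channel raw sEMG session (channels BB, BRA, TRI, DEL at
#' 1000 Hz), three MVC calibration trial values per channel, and a stream
#' of timestamped Borg self-reports. Deterministic for a fixed profile
#' seed.
#'
#' @param profile a [subject_profile()].
#' @param fs sampling frequency in Hz.
#' @return an object of class `semg_recording` with fields `subject_id`,
#'   `fs`, `channel_names`, `signal` (channels x samples matrix, mV),
#'   `mvc_trials` (named list, 3 values per channel), `borg_reports`
#'   (data.frame `time_s`, `score`), `duration_s`, `stage = "raw"`.
#' @export
simulate_subject <- function(profile, fs = 1000) {
  check_that(inherits(profile, "semg_subject_profile"),
             "profile must be a semg_subject_profile")
  n <- round(profile$duration_s * fs)
  check_that(n >= 1, "duration too short")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(profile$seed)

  signal <- matrix(0, nrow = length(semg_channels), ncol = n,
                   dimnames = list(semg_channels, NULL))
  mvc_trials <- stats::setNames(vector("list", length(semg_channels)),
                                semg_channels)
  lp10 <- filter_spec("lowpass", cutoff_hz = 10)
  for (ch in seq_along(semg_channels)) {
    # mild per-channel amplitude heterogeneity (synergists fire less)
    ch_scale <- c(1, 0.8, 0.6, 0.7)[ch]
    chp <- profile
    chp$baseline_rms <- profile$baseline_rms * ch_scale
    chp$noise_floor <- profile$noise_floor
    if (chp$baseline_rms > 0 || chp$noise_floor > 0) {
      signal[ch, ] <- simulate_trace(n, fs, chp)
    }
    # MVC protocol: three 5 s maximal contractions; the trial value is the
    # peak of the linear envelope of each maximal-effort segment
    trial_n <- 5 * fs
    vals <- numeric(3)
    for (k in 1:3) {
      mp <- chp
      mp$baseline_rms <- max(chp$baseline_rms * profile$mvc_gain, 1e-12)
      mp$rms_gain_end <- 1
      tr <- simulate_trace(trial_n, fs, mp)
      vals[k] <- max(linear_envelope(tr, fs, lp10))
    }
    mvc_trials[[ch]] <- vals
  }

  rep_s <- profile$rep_period_s * profile$borg_every_reps
  times <- if (rep_s <= profile$duration_s) {
    seq(rep_s, profile$duration_s, by = rep_s)
  } else numeric(0)
  # pre-task baseline rating at t = 0, then one report per reporting cycle
  times <- c(0, times)
  borg <- data.frame(
    time_s = times,
    score = borg_trajectory(pmin(times / profile$duration_s, 1), profile)
  )

  structure(list(subject_id = profile$subject_id, fs = fs,
                 channel_names = semg_channels, signal = signal,
                 mvc_trials = mvc_trials, borg_reports = borg,
                 duration_s = profile$duration_s, stage = "raw",
                 profile = profile),
            class = "semg_recording")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a cohort of subjects
#'
#' Each subject receives a jittered copy of the base profile
#' (inter-subject variability in amplitude, gain, spectral schedule,
#' session length and Borg reporting) and an independent random substream
#' derived by stable hashing of the subject id, so a cohort is
#' reproducible regardless of generation order.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param base_profile the cohort-level [subject_profile()].
#' @param seed master seed.
#' @return list of `semg_recording`, one per subject, with unique ids.
#' @export
simulate_cohort <- function(n_subjects = 20,
                            base_profile = subject_profile(),
                            seed = 1L) {
  check_that(n_subjects >= 1, "n_subjects must be >= 1")
  lapply(seq_len(n_subjects), function(i) {
    id <- sprintf("S%02d", i)
    sub_seed <- derive_seed(seed, id)
    old <- .Random.seed_save()
    set.seed(sub_seed)
    p <- base_profile
    p$subject_id <- id
    if (n_subjects > 1) {
      p$baseline_rms <- base_profile$baseline_rms * exp(stats::rnorm(1, 0, 0.15))
      p$rms_gain_end <- max(1.1, base_profile$rms_gain_end *
                              (1 + stats::rnorm(1, 0, 0.1)))
      p$mnf_start <- min(440, max(30, base_profile$mnf_start +
                                    stats::rnorm(1, 0, 6)))
      p$mnf_end <- min(p$mnf_start, max(25, base_profile$mnf_end +
                                          stats::rnorm(1, 0, 5)))
      p$duration_s <- max(30, base_profile$duration_s *
                            (1 + stats::rnorm(1, 0, 0.08)))
      # subjects differ in how early they report fatigue; this is what
      # produces phase/Borg disagreements and hence upgraded labels
      p$borg_shape <- base_profile$borg_shape * exp(stats::rnorm(1, 0, 0.2))
    }
    p$seed <- derive_seed(sub_seed, "signal")
    .Random.seed_restore(old)
    simulate_subject(p)
  })
}
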