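# Independent, loop-based oracle implementations used to check the
# package's vectorized feature code, plus small fixture builders. These
# deliberately avoid the code paths they verify.

oracle_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  sqrt(s / length(x))
}

oracle_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

oracle_wl <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])
  s
}

oracle_zc <- function(x, thr) {
  n <- 0
  for (i in 1:(length(x) - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i + 1] - x[i]) >= thr) n <- n + 1
  }
  n
}

oracle_wamp <- function(x, thr) {
  n <- 0
  for (i in 1:(length(x) - 1)) {
    if (abs(x[i] - x[i + 1]) >= thr) n <- n + 1
  }
  n
}

oracle_mnf <- function(freqs, power) {
  num <- 0
  den <- 0
  for (i in seq_along(freqs)) {
    num <- num + freqs[i] * power[i]
    den <- den + power[i]
  }
  num / den
}

# half-power crossing with bin-centered mass, written as an explicit
# scan: bin i spans halfway to each neighboring frequency and its power
# is uniform over that span
oracle_mdf <- function(freqs, power) {
  n <- length(freqs)
  if (n == 1) return(freqs[1])
  half <- sum(power) / 2
  cum <- 0
  for (i in seq_len(n)) {
    lo <- if (i == 1) freqs[1] - (freqs[2] - freqs[1]) / 2
          else (freqs[i - 1] + freqs[i]) / 2
    hi <- if (i == n) freqs[n] + (freqs[n] - freqs[n - 1]) / 2
          else (freqs[i] + freqs[i + 1]) / 2
    if (cum + power[i] >= half) {
      return(lo + (half - cum) / power[i] * (hi - lo))
    }
    cum <- cum + power[i]
  }
  freqs[n]
}

# raw-moment Hu oracle: direct double-loop moment summation
oracle_hu <- function(g) {
  h <- nrow(g)
  w <- ncol(g)
  m <- function(p, q) {
    s <- 0
    for (yy in 1:h) for (xx in 1:w) s <- s + xx^p * yy^q * g[yy, xx]
    s
  }
  m00 <- m(0, 0)
  xb <- m(1, 0) / m00
  yb <- m(0, 1) / m00
  mu <- function(p, q) {
    s <- 0
    for (yy in 1:h) for (xx in 1:w) {
      s <- s + (xx - xb)^p * (yy - yb)^q * g[yy, xx]
    }
    s
  }
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

# brute-force sliding-window start enumeration
oracle_window_starts <- function(l_ms, window_ms, hop_ms) {
  starts <- c()
  s <- 0
  while (s + window_ms <= l_ms) {
    starts <- c(starts, s)
    s <- s + hop_ms
  }
  starts
}

# minimal recording fixture without the simulator
make_recording <- function(n_samples, fs = 1000, n_channels = 4,
                           subject_id = "T01", signal = NULL,
                           borg = data.frame(time_s = 0, score = 0L)) {
  chans <- c("BB", "BRA", "TRI", "DEL")[seq_len(n_channels)]
  if (is.null(signal)) {
    signal <- matrix(stats::rnorm(n_channels * n_samples, sd = 0.05),
                     n_channels, n_samples, dimnames = list(chans, NULL))
  }
  structure(list(subject_id = subject_id, fs = fs, channel_names = chans,
                 signal = signal,
                 mvc_trials = stats::setNames(
                   rep(list(c(0.2, 0.25, 0.3)), n_channels), chans),
                 borg_reports = borg,
                 duration_s = n_samples / fs, stage = "raw"),
            class = "semg_recording")
}

# cached small cohort shared by several test files
semg_test_env <- new.env(parent = emptyenv())
cached_cohort <- function(n = 5, duration_s = 30, seed = 11) {
  key <- paste("cohort", n, duration_s, seed, sep = "_")
  if (is.null(semg_test_env[[key]])) {
    semg_test_env[[key]] <-
      simulate_cohort(n, subject_profile(duration_s = duration_s),
                      seed = seed)
  }
  semg_test_env[[key]]
}
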