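# Signal conditioning: Butterworth band-pass noise reduction, linear
# envelope extraction (full-wave rectification + low-pass), and MVC
# normalization.
#
# Filter design follows the classical analog-prototype + bilinear-transform
# route (identical to the design used by scipy.signal.butter / MATLAB
# butter), implemented here because no DSP package is available at runtime.

#' Describe a Butterworth filter
#'
#' @param kind `"bandpass"` or `"lowpass"`.
#' @param order design order of the low-pass prototype. A band-pass of
#'   design order 4 has 8 poles (4 conjugate pole pairs), the conventional
#'   reading of "4th-order band-pass" in the sEMG literature.
#' @param low_hz,high_hz band edges in Hz (band-pass only).
#' @param cutoff_hz cutoff in Hz (low-pass only).
#' @param zero_phase apply the filter forward and backward (no phase
#'   distortion; attenuation is applied twice).
#' @return an object of class `semg_filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "lowpass"), order = 4L,
                        low_hz = 20, high_hz = 450, cutoff_hz = 10,
                        zero_phase = TRUE) {
  kind <- match.arg(kind)
  check_that(order >= 1, "filter order must be >= 1")
  if (kind == "bandpass") {
    check_that(low_hz > 0 && low_hz < high_hz,
               "bandpass requires 0 < low_hz < high_hz")
  } else {
    check_that(cutoff_hz > 0, "lowpass requires cutoff_hz > 0")
  }
  structure(list(kind = kind, order = as.integer(order), low_hz = low_hz,
                 high_hz = high_hz, cutoff_hz = cutoff_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "semg_filter_spec")
}

# -- Butterworth design ------------------------------------------------------

# polynomial coefficients (descending powers) from complex roots
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (root in r) p <- c(p, 0i) - c(0i, p * root)
  p
}

#' Design digital Butterworth filter coefficients
#'
#' Returns transfer-function coefficients `b` (numerator) and `a`
#' (denominator) for a low-pass or band-pass Butterworth filter, using the
#' analog prototype, frequency pre-warping and the bilinear transform. The
#' -3 dB corners land exactly on the requested edge frequencies.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling frequency in Hz.
#' @return list with numeric vectors `b` and `a` (`a[1] == 1`).
#' @export
butter_coefficients <- function(spec, fs) {
  n <- spec$order
  if (spec$kind == "bandpass") {
    check_that(spec$high_hz < fs / 2,
               "bandpass high edge must be below Nyquist",
               class = "semg_design_error")
    wn <- c(spec$low_hz, spec$high_hz) / (fs / 2)
  } else {
    check_that(spec$cutoff_hz < fs / 2,
               "lowpass cutoff must be below Nyquist",
               class = "semg_design_error")
    wn <- spec$cutoff_hz / (fs / 2)
  }
  fs2 <- 2                      # normalized design rate
  warped <- 2 * fs2 * tan(pi * wn / fs2)

  # analog low-pass prototype: n left-half-plane poles on the unit circle
  m <- seq(-n + 1, n - 1, by = 2)
  p <- -exp(1i * pi * m / (2 * n))
  z <- complex(0)
  k <- 1

  if (spec$kind == "lowpass") {
    wo <- warped
    p <- p * wo
    k <- k * wo^n
  } else {
    bw <- warped[2] - warped[1]
    wo <- sqrt(warped[1] * warped[2])
    s <- p * bw / 2
    p <- c(s + sqrt(s^2 - wo^2), s - sqrt(s^2 - wo^2))
    z <- rep(0 + 0i, n)
    k <- k * bw^n
  }

  # bilinear transform (fs2 normalized rate)
  f2 <- 2 * fs2
  degree <- length(p) - length(z)
  zd <- (f2 + z) / (f2 - z)
  pd <- (f2 + p) / (f2 - p)
  kd <- k * Re(prod(f2 - z) / prod(f2 - p))
  zd <- c(zd, rep(-1 + 0i, degree))

  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

#' Magnitude response of a digital filter
#'
#' @param coef list with `b`, `a` as from [butter_coefficients()].
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling frequency in Hz.
#' @return `|H(e^{i 2 pi f / fs})|` at each frequency.
#' @export
filter_gain <- function(coef, f, fs) {
  w <- 2 * pi * f / fs
  eval_poly <- function(cf, zinv) {
    acc <- rep(0 + 0i, length(zinv))
    for (c_k in cf) acc <- acc * zinv + c_k
    acc
  }
  # H(z) = B(z^-1)/A(z^-1) with coefficients in ascending delay order
  zinv <- exp(-1i * w)
  num <- eval_poly(rev(coef$b), 1 / zinv) * zinv^(length(coef$b) - 1)
  den <- eval_poly(rev(coef$a), 1 / zinv) * zinv^(length(coef$a) - 1)
  Mod(num / den)
}

# single-pass IIR filtering, zero initial state (vectorized via stats::filter)
iir_filter <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# forward-backward filtering with odd (anti-symmetric) edge extension to
# suppress start-up transients
filtfilt_odd <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1, max(3 * (max(length(a), length(b)) - 1), 50))
  if (pad > 0) {
    front <- 2 * x[1] - x[seq(pad + 1, 2)]
    back <- 2 * x[n] - x[seq(n - 1, n - pad)]
    ext <- c(front, x, back)
  } else {
    ext <- x
  }
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

apply_filter <- function(signal, fs, spec) {
  coef <- butter_coefficients(spec, fs)
  if (spec$zero_phase) filtfilt_odd(coef$b, coef$a, signal)
  else iir_filter(coef$b, coef$a, signal)
}

# -- user-facing stages ------------------------------------------------------

#' Band-pass filter an sEMG trace
#'
#' Applies the 20-450 Hz (by default) Butterworth band-pass used to remove
#' baseline drift and electrode-motion artefacts before any analysis.
#'
#' @param signal numeric vector, raw sEMG in mV.
#' @param fs sampling frequency in Hz.
#' @param spec a band-pass [filter_spec()].
#' @return filtered vector of the same length.
#' @export
bandpass_filter <- function(signal, fs, spec = filter_spec("bandpass")) {
  check_that(spec$kind == "bandpass", "spec must be a bandpass filter_spec")
  check_finite(signal, "signal")
  check_that(length(signal) > 3 * spec$order,
             "signal too short for the requested filter order")
  apply_filter(signal, fs, spec)
}

#' Linear envelope of an sEMG trace
#'
#' Full-wave rectification followed by a low-pass Butterworth filter
#' (10 Hz cutoff by default). Negative low-pass overshoot is clipped to
#' zero: an amplitude envelope is non-negative by definition.
#'
#' @inheritParams bandpass_filter
#' @param spec a low-pass [filter_spec()].
#' @return non-negative envelope vector of the same length, in mV.
#' @export
linear_envelope <- function(signal, fs,
                            spec = filter_spec("lowpass", cutoff_hz = 10)) {
  check_that(spec$kind == "lowpass", "spec must be a lowpass filter_spec")
  check_finite(signal, "signal")
  env <- apply_filter(abs(signal), fs, spec)
  pmax(env, 0)
}

#' Per-channel MVC normalization reference
#'
#' The protocol records three 5-second maximal voluntary contractions per
#' channel; their arithmetic mean is the normalization reference.
#'
#' @param mvc_trials numeric vector of 3 trial maxima (one channel) or a
#'   matrix/list with 3 values per channel.
#' @return scalar per channel (named numeric if input has names).
#' @export
mvc_reference <- function(mvc_trials) {
  one <- function(v) {
    check_that(length(v) == 3, "exactly 3 MVC trials per channel required")
    check_that(all(v > 0), "MVC trial values must be positive")
    mean(v)
  }
  if (is.list(mvc_trials)) vapply(mvc_trials, one, numeric(1))
  else if (is.matrix(mvc_trials)) apply(mvc_trials, 2, one)
  else one(mvc_trials)
}

#' Normalize a trace by its MVC reference
#'
#' @param signal numeric vector.
#' @param mvc_ref positive scalar (mV).
#' @return signal expressed as a fraction of MVC (multiply by 100 for %MVC).
#' @export
normalize_mvc <- function(signal, mvc_ref) {
  check_that(is.numeric(mvc_ref) && length(mvc_ref) == 1 && mvc_ref > 0,
             "mvc_ref must be a positive scalar")
  signal / mvc_ref
}

#' Run the full conditioning chain on a recording
#'
#' Band-pass filters every channel, computes the linear envelope, and
#' normalizes by the per-channel MVC reference. Frequency-domain analysis
#' (features, scalograms) consumes the band-passed MVC-normalized signal;
#' the 10 Hz envelope cannot carry 20-450 Hz spectral content and is kept
#' for amplitude inspection only.
#'
#' @param recording a `semg_recording` (see [simulate_subject()] or
#'   [read_recording()]).
#' @param bandpass band-pass [filter_spec()].
#' @param envelope low-pass [filter_spec()] for the envelope stage.
#' @return a `semg_recording` with `stage = "normalized"`, the conditioned
#'   `signal` matrix (fraction of MVC), an `envelope` matrix (fraction of
#'   MVC) and the `mvc_reference` used.
#' @export
preprocess_recording <- function(recording,
                                 bandpass = filter_spec("bandpass"),
                                 envelope = filter_spec("lowpass",
                                                        cutoff_hz = 10)) {
  check_that(inherits(recording, "semg_recording"),
             "recording must be a semg_recording")
  check_that(identical(recording$stage, "raw"),
             "recording has already been processed")
  fs <- recording$fs
  mvc <- mvc_reference(recording$mvc_trials)
  out_sig <- recording$signal
  out_env <- recording$signal
  for (ch in seq_len(nrow(recording$signal))) {
    bp <- bandpass_filter(recording$signal[ch, ], fs, bandpass)
    out_sig[ch, ] <- normalize_mvc(bp, mvc[[ch]])
    out_env[ch, ] <- normalize_mvc(linear_envelope(bp, fs, envelope),
                                   mvc[[ch]])
  }
  recording$signal <- out_sig
  recording$envelope <- out_env
  recording$mvc_reference <- mvc
  recording$stage <- "normalized"
  recording
}
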