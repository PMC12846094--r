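# The eight classical sEMG features computed per channel window:
# time-domain amplitude (RMS, MAV, WL), threshold-gated event counts
# (ZC, WAMP) and spectral statistics (MNF, MPF, MDF) of the window's
# power spectral density. Four channels x eight features give the
# 32-dimensional vector consumed by the classical baselines.

#' Feature extraction configuration
#'
#' @param threshold_mv threshold for the zero-crossing and Willison
#'   amplitude counts (0.1 mV by convention; when features are computed on
#'   MVC-normalized signals the threshold is interpreted in the same
#'   normalized units).
#' @param psd_method `"periodogram"` (single Hann-tapered periodogram) or
#'   `"welch"` (averaged over 50%-overlapping Hann segments).
#' @param welch_segments number of Welch segments.
#' @param feature_order permutation of the 8 feature names.
#' @return an object of class `semg_feature_config`.
#' @export
feature_config <- function(threshold_mv = 0.1,
                           psd_method = c("periodogram", "welch"),
                           welch_segments = 8,
                           feature_order = c("RMS", "MAV", "ZC", "MNF",
                                             "MPF", "WL", "MDF", "WAMP")) {
  psd_method <- match.arg(psd_method)
  check_that(threshold_mv > 0, "threshold_mv must be positive")
  check_that(setequal(feature_order, c("RMS", "MAV", "ZC", "MNF", "MPF",
                                       "WL", "MDF", "WAMP")) &&
               length(feature_order) == 8,
             "feature_order must be a permutation of the 8 feature names")
  structure(list(threshold_mv = threshold_mv, psd_method = psd_method,
                 welch_segments = welch_segments,
                 feature_order = feature_order),
            class = "semg_feature_config")
}

#' Root mean square of a window
#' @param window numeric vector of samples.
#' @return `sqrt(sum(x^2) / K)`.
#' @export
emg_rms <- function(window) {
  check_that(length(window) >= 1, "empty window")
  sqrt(mean(window^2))
}

#' Mean absolute value of a window
#' @param window numeric vector of samples.
#' @return `sum(|x|) / K` (unit weights).
#' @export
emg_mav <- function(window) {
  check_that(length(window) >= 1, "empty window")
  mean(abs(window))
}

#' Waveform length of a window
#' @param window numeric vector of samples (length >= 2).
#' @return cumulative length `sum(|x_i - x_{i-1}|)`.
#' @export
emg_wl <- function(window) {
  check_that(length(window) >= 2, "window must have at least 2 samples")
  sum(abs(diff(window)))
}

#' Threshold-gated zero-crossing count
#'
#' Counts adjacent sample pairs with a sign change whose jump exceeds the
#' threshold: `x_i * x_{i+1} < 0` and `|x_{i+1} - x_i| >= thr`.
#'
#' @param window numeric vector (length >= 2).
#' @param threshold gate in the window's amplitude units.
#' @return integer count in `[0, K-1]`.
#' @export
emg_zc <- function(window, threshold = 0.1) {
  check_that(length(window) >= 2, "window must have at least 2 samples")
  check_that(threshold > 0, "threshold must be positive")
  a <- window[-length(window)]
  b <- window[-1]
  sum(a * b < 0 & abs(b - a) >= threshold)
}

#' Willison amplitude
#'
#' Counts adjacent sample pairs whose absolute difference reaches the
#' threshold: `|x_i - x_{i+1}| >= thr`.
#'
#' @inheritParams emg_zc
#' @return integer count in `[0, K-1]`.
#' @export
emg_wamp <- function(window, threshold = 0.1) {
  check_that(length(window) >= 2, "window must have at least 2 samples")
  check_that(threshold > 0, "threshold must be positive")
  sum(abs(diff(window)) >= threshold)
}

#' One-sided power spectral density of a window
#'
#' Hann-tapered periodogram (or Welch average), scaled so that
#' `sum(power) * df` equals the taper-corrected mean signal power
#' (Parseval consistency).
#'
#' @param window numeric vector of samples (length >= 8).
#' @param fs sampling frequency in Hz.
#' @param config a [feature_config()].
#' @return a `semg_spectrum`: list with `freqs` (Hz, strictly increasing)
#'   and `power` (non-negative density values).
#' @export
power_spectrum <- function(window, fs, config = feature_config()) {
  k <- length(window)
  check_that(k >= 8, "window too short for spectral estimation")
  one_pgram <- function(x) {
    nn <- length(x)
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nn - 1) / (nn - 1))
    xf <- stats::fft(x * w)
    nfreq <- nn %/% 2 + 1
    p <- Mod(xf[seq_len(nfreq)])^2 / (fs * sum(w^2))
    # one-sided: double everything except DC (and Nyquist when n even)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nn %% 2 == 0) dbl[nfreq] <- 1
    list(freqs = (seq_len(nfreq) - 1) * fs / nn, power = p * dbl)
  }
  if (config$psd_method == "periodogram") {
    sp <- one_pgram(window)
  } else {
    nseg <- max(2, config$welch_segments)
    seg_len <- max(8, 2 * (k %/% (nseg + 1)))
    hop <- seg_len %/% 2
    starts <- seq(1, k - seg_len + 1, by = hop)
    acc <- NULL
    for (s0 in starts) {
      pg <- one_pgram(window[s0:(s0 + seg_len - 1)])
      acc <- if (is.null(acc)) pg$power else acc + pg$power
    }
    sp <- list(freqs = pg$freqs, power = acc / length(starts))
  }
  structure(sp, class = "semg_spectrum")
}

#' Mean (centroid) frequency of a power spectrum
#'
#' `sum(f * P) / sum(P)`. The mean power frequency (MPF) is the same
#' centroid written in integral form; [spec_mpf()] computes it on the
#' same discrete density so both occupy their own slot in the feature
#' vector with identical numerics.
#'
#' @param spectrum a `semg_spectrum` from [power_spectrum()].
#' @return frequency in Hz, between `min(freqs)` and `max(freqs)`.
#' @export
spec_mnf <- function(spectrum) {
  tot <- sum(spectrum$power)
  if (!is.finite(tot) || tot <= 0) {
    abort_validation("zero-power spectrum: mean frequency undefined",
                     class = "semg_undefined_feature")
  }
  sum(spectrum$freqs * spectrum$power) / tot
}

#' Mean power frequency (continuous-form spectral centroid)
#' @inheritParams spec_mnf
#' @return frequency in Hz.
#' @export
spec_mpf <- function(spectrum) spec_mnf(spectrum)

#' Median (half-power) frequency of a power spectrum
#'
#' The frequency at which cumulative power crosses half the total. Each
#' bin's power is treated as spread uniformly over a bin centered on its
#' frequency (edges halfway to the neighboring bins), and the crossing
#' point is found by linear interpolation inside the crossing bin. A
#' single spectral line therefore returns its own frequency, and two
#' equal lines at 50 and 150 Hz return the midpoint 100 Hz.
#'
#' @inheritParams spec_mnf
#' @return frequency in Hz.
#' @export
spec_mdf <- function(spectrum) {
  tot <- sum(spectrum$power)
  if (!is.finite(tot) || tot <= 0) {
    abort_validation("zero-power spectrum: median frequency undefined",
                     class = "semg_undefined_feature")
  }
  f <- spectrum$freqs
  n <- length(f)
  mids <- (f[-n] + f[-1]) / 2
  lo <- c(f[1] - (mids[1] - f[1]), mids)         # lower bin edges
  hi <- c(mids, f[n] + (f[n] - mids[n - 1]))     # upper bin edges
  if (n == 1) return(f[1])
  cum <- cumsum(spectrum$power)
  half <- tot / 2
  i <- which(cum >= half)[1]
  c0 <- if (i == 1) 0 else cum[i - 1]
  lo[i] + (half - c0) / spectrum$power[i] * (hi[i] - lo[i])
}

#' Compute the 8 features of one window
#'
#' @param window numeric vector of samples.
#' @param fs sampling frequency in Hz.
#' @param config a [feature_config()].
#' @return named numeric vector in `config$feature_order`; spectral
#'   features of a zero-power window are `NA` (missing sentinel; such
#'   rows are dropped before model fitting).
#' @export
window_features <- function(window, fs, config = feature_config()) {
  thr <- config$threshold_mv
  vals <- c(RMS = emg_rms(window), MAV = emg_mav(window),
            ZC = as.numeric(emg_zc(window, thr)),
            WL = emg_wl(window),
            WAMP = as.numeric(emg_wamp(window, thr)))
  spec_vals <- tryCatch({
    sp <- power_spectrum(window, fs, config)
    c(MNF = spec_mnf(sp), MPF = spec_mpf(sp), MDF = spec_mdf(sp))
  }, semg_undefined_feature = function(e) c(MNF = NA_real_, MPF = NA_real_,
                                            MDF = NA_real_))
  out <- c(vals, spec_vals)[config$feature_order]
  names(out) <- config$feature_order
  out
}

#' Assemble the 32-dimensional feature vector of one multi-channel window
#'
#' @param channel_windows named list of 4 numeric windows (one per
#'   channel, same start time), in channel order.
#' @param fs sampling frequency in Hz.
#' @param config a [feature_config()].
#' @param channel_order expected channel names.
#' @return named numeric vector of length `4 * 8 = 32`, channel-major
#'   (all of BB's features, then BRA's, TRI's, DEL's).
#' @export
feature_vector <- function(channel_windows, fs, config = feature_config(),
                           channel_order = semg_channels) {
  check_that(all(channel_order %in% names(channel_windows)),
             "missing channel in channel_windows")
  out <- unlist(lapply(channel_order, function(ch) {
    v <- window_features(channel_windows[[ch]], fs, config)
    names(v) <- paste(ch, names(v), sep = "_")
    v
  }))
  check_that(length(out) == 8 * length(channel_order),
             "unexpected feature vector length")
  out
}

#' Feature matrix for a labeled dataset
#'
#' Groups the per-channel segments of each (subject, start_ms) window,
#' computes the 32-dimensional vector, and returns it with the window's
#' label and provenance metadata.
#'
#' @param dataset a labeled `semg_dataset` (see [label_segments()]).
#' @param config a [feature_config()].
#' @return list with `x` (matrix, one row per window), `meta` (data.frame
#'   subject_id, start_ms, task_progress, borg, class, label_source) and
#'   `n_dropped` (windows removed for undefined spectral features).
#' @export
feature_matrix <- function(dataset, config = feature_config()) {
  idx <- dataset$index
  key <- paste(idx$subject_id, idx$start_ms)
  groups <- split(seq_len(nrow(idx)), key)
  # preserve original window order
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  rows <- vector("list", length(groups))
  meta <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    ii <- groups[[g]]
    wins <- stats::setNames(dataset$samples[ii], idx$channel[ii])
    rows[[g]] <- feature_vector(wins, dataset$fs, config,
                                channel_order = unique(idx$channel[ii]))
    meta[[g]] <- idx[ii[1], c("subject_id", "start_ms", "task_progress",
                              "borg", "class", "label_source")]
  }
  x <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  keep <- stats::complete.cases(x)
  list(x = x[keep, , drop = FALSE], meta = meta[keep, , drop = FALSE],
       n_dropped = sum(!keep))
}
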