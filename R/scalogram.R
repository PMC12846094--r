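# Continuous wavelet transform of windowed sEMG with the (analytic)
# Morlet mother wavelet, rendered as fixed-size 3-channel scalogram
# images, plus the Haralick / Hu texture-and-shape descriptors used in
# the "classical classifier on scalogram features" ablation.

#' CWT configuration
#'
#' @param wavelet mother wavelet (only `"morlet"` is implemented).
#' @param n_scales number of scales; the scale grid is linear `1..n_scales`
#'   in samples, giving an `n_scales`-row scalogram (256 by default).
#' @param omega0 Morlet center frequency parameter (dimensionless; 6 is
#'   the standard admissible choice).
#' @param magnitude return absolute coefficient values.
#' @return an object of class `semg_cwt_config`.
#' @export
cwt_config <- function(wavelet = "morlet", n_scales = 256L, omega0 = 6,
                       magnitude = TRUE) {
  check_that(identical(wavelet, "morlet"), "only the Morlet wavelet is implemented")
  check_that(n_scales >= 2, "n_scales must be >= 2")
  structure(list(wavelet = wavelet, n_scales = as.integer(n_scales),
                 omega0 = omega0, magnitude = isTRUE(magnitude)),
            class = "semg_cwt_config")
}

#' Peak (pseudo-)frequency of the Morlet wavelet at a given scale
#'
#' The Fourier transform of the Morlet wavelet at scale `a` peaks at
#' angular frequency `omega0 / a`; in Hz, with scales measured in
#' samples, `f = omega0 * fs / (2 * pi * a)`.
#'
#' @param scales scale values in samples.
#' @param fs sampling frequency in Hz.
#' @param omega0 Morlet parameter.
#' @return frequencies in Hz.
#' @export
morlet_scale_to_freq <- function(scales, fs, omega0 = 6) {
  omega0 * fs / (2 * pi * scales)
}

#' Continuous wavelet transform of one window
#'
#' FFT-based CWT with the analytic Morlet wavelet on a linear scale grid.
#' The signal is symmetrically extended (mirror padding) before the
#' circular convolution, so edge columns see reflected data rather than
#' wrap-around.
#'
#' @param window numeric vector of samples (one channel window), or a
#'   segment's `samples`.
#' @param fs sampling frequency in Hz.
#' @param config a [cwt_config()].
#' @return a `semg_scalogram`: list with `coefficients`
#'   (`n_scales x n_samples`, non-negative magnitudes), `scales`
#'   (samples), `freqs` (Hz, pseudo-frequency per scale) and `times_ms`.
#' @export
cwt_morlet <- function(window, fs, config = cwt_config()) {
  n <- length(window)
  check_that(n >= 2, "window must be non-empty")
  check_finite(window, "window")
  scales <- seq_len(config$n_scales)
  check_that(n >= 2 * max(scales),
             "window shorter than the largest wavelet support; reduce n_scales")
  ext <- c(window, rev(window))            # mirror extension
  nfft <- length(ext)
  xf <- stats::fft(ext)
  k <- seq_len(nfft) - 1
  omega <- 2 * pi * ifelse(k <= nfft / 2, k, k - nfft) / nfft * fs
  pos <- omega > 0
  w0 <- config$omega0
  coef <- matrix(0, nrow = length(scales), ncol = n)
  for (si in seq_along(scales)) {
    a_sec <- scales[si] / fs
    psi <- numeric(nfft)
    psi[pos] <- pi^(-1 / 4) * sqrt(2 * pi * a_sec * fs) *
      exp(-(a_sec * omega[pos] - w0)^2 / 2)
    row <- stats::fft(xf * psi, inverse = TRUE)[seq_len(n)] / nfft
    coef[si, ] <- if (config$magnitude) Mod(row) else Re(row)
  }
  structure(list(coefficients = coef, scales = scales,
                 freqs = morlet_scale_to_freq(scales, fs, w0),
                 times_ms = (seq_len(n) - 1) / fs * 1000),
            class = "semg_scalogram")
}

# bilinear resize of a matrix to (h, w), pixel-center aligned
resize_bilinear <- function(mat, h, w) {
  interp_weights <- function(n_out, n_in) {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    src <- pmin(pmax(src, 1), n_in)
    lo <- pmin(floor(src), n_in - 1)
    if (n_in == 1) lo <- rep(1, n_out)
    frac <- src - lo
    m <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      m[i, lo[i]] <- 1 - frac[i]
      m[i, min(lo[i] + 1, n_in)] <- m[i, min(lo[i] + 1, n_in)] + frac[i]
    }
    m
  }
  rw <- interp_weights(h, nrow(mat))
  cw <- interp_weights(w, ncol(mat))
  rw %*% mat %*% t(cw)
}

semg_colormap <- function(n = 256) {
  hex <- viridisLite::viridis(n)
  t(grDevices::col2rgb(hex))        # n x 3 integer matrix
}

#' Render a scalogram as a fixed-size 3-channel image
#'
#' Coefficient magnitudes are min-max normalized per image, bilinearly
#' resized, and mapped through a fixed perceptual colormap (viridis) to
#' produce the three channels expected by an image classifier. A
#' degenerate all-equal coefficient matrix renders as a uniform
#' mid-colormap image.
#'
#' @param scalogram a `semg_scalogram` from [cwt_morlet()].
#' @param height,width output size in pixels (224 x 224 by default).
#' @return a `semg_scalogram_image`: list with `pixels` (integer array
#'   `height x width x 3` in 0..255), `colormap_id` and `normalization`.
#' @export
render_image <- function(scalogram, height = 224L, width = 224L) {
  check_that(inherits(scalogram, "semg_scalogram"),
             "scalogram must be a semg_scalogram")
  co <- scalogram$coefficients
  rng <- range(co)
  if (diff(rng) <= 0) {
    norm <- matrix(0.5, nrow(co), ncol(co))
  } else {
    norm <- (co - rng[1]) / (rng[2] - rng[1])
  }
  rs <- resize_bilinear(norm, height, width)
  rs <- pmin(pmax(rs, 0), 1)
  cmap <- semg_colormap(256)
  idx <- matrix(as.integer(round(rs * 255)) + 1L, height, width)
  px <- array(0L, dim = c(height, width, 3))
  for (ch in 1:3) px[, , ch] <- matrix(cmap[idx, ch], height, width)
  structure(list(pixels = px, height = height, width = width,
                 colormap_id = "viridis", normalization = "per_image_minmax"),
            class = "semg_scalogram_image")
}

image_grayscale <- function(image) {
  px <- image$pixels
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

# symmetric normalized gray-level co-occurrence matrix for one offset
glcm_one <- function(q, n_levels, dy, dx) {
  h <- nrow(q)
  w <- ncol(q)
  r0 <- max(1, 1 - dy):min(h, h - dy)
  c0 <- max(1, 1 - dx):min(w, w - dx)
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + dy, c0 + dx, drop = FALSE]
  m <- matrix(0, n_levels, n_levels)
  tab <- table(factor(a, levels = 1:n_levels), factor(b, levels = 1:n_levels))
  m <- m + tab + t(tab)
  m / sum(m)
}

haralick_one <- function(p) {
  ng <- nrow(p)
  i <- row(p)
  j <- col(p)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum((1:ng) * px)
  muy <- sum((1:ng) * py)
  sdx <- sqrt(sum(((1:ng) - mux)^2 * px))
  sdy <- sqrt(sum(((1:ng) - muy)^2 * py))
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(p[i + j == k]), numeric(1))
  pxy_dif <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]),
                    numeric(1))
  ent <- function(v) {
    v <- v[v > 0]
    -sum(v * log(v))
  }
  f1 <- sum(p^2)
  f2 <- sum((0:(ng - 1))^2 * pxy_dif)
  f3 <- if (sdx > 0 && sdy > 0) (sum(i * j * p) - mux * muy) / (sdx * sdy)
        else 0
  f4 <- sum((i - mux)^2 * p)
  f5 <- sum(p / (1 + (i - j)^2))
  f6 <- sum((2:(2 * ng)) * pxy_sum)
  f7 <- sum(((2:(2 * ng)) - f6)^2 * pxy_sum)
  f8 <- ent(pxy_sum)
  f9 <- ent(p)
  kd <- 0:(ng - 1)
  mud <- sum(kd * pxy_dif)
  f10 <- sum((kd - mud)^2 * pxy_dif)
  f11 <- ent(pxy_dif)
  hx <- ent(px)
  hy <- ent(py)
  ppxy <- outer(px, py)
  sel <- p > 0 & ppxy > 0
  hxy1 <- -sum(p[sel] * log(ppxy[sel]))
  hxy2 <- ent(ppxy)
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f9))))
  c(asm = f1, contrast = f2, correlation = f3, variance = f4, idm = f5,
    sum_average = f6, sum_variance = f7, sum_entropy = f8, entropy = f9,
    diff_variance = f10, diff_entropy = f11, imc1 = f12, imc2 = f13)
}

#' Hu invariant moments of a grayscale matrix
#'
#' @param g numeric matrix (intensities).
#' @return the seven Hu moment invariants.
#' @export
hu_moments <- function(g) {
  h <- nrow(g)
  w <- ncol(g)
  x <- matrix(rep(seq_len(w), each = h), h, w)   # column index
  y <- matrix(rep(seq_len(h), times = w), h, w)  # row index
  m00 <- sum(g)
  if (m00 == 0) return(stats::setNames(numeric(7), paste0("hu", 1:7)))
  xb <- sum(x * g) / m00
  yb <- sum(y * g) / m00
  mu <- function(p, q) sum((x - xb)^p * (y - yb)^q * g)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  stats::setNames(c(h1, h2, h3, h4, h5, h6, h7), paste0("hu", 1:7))
}

#' Texture and shape features of a scalogram image
#'
#' 13 Haralick co-occurrence statistics (averaged over the four standard
#' directions, 32 gray levels) plus the 7 Hu invariant moments, computed
#' on the grayscale-converted image.
#'
#' @param image a `semg_scalogram_image` from [render_image()].
#' @param n_levels number of gray levels for the co-occurrence matrix.
#' @return named numeric vector of length 20.
#' @export
texture_features <- function(image, n_levels = 32) {
  check_that(inherits(image, "semg_scalogram_image"),
             "image must be a semg_scalogram_image")
  g <- image_grayscale(image)
  q <- matrix(pmin(floor(g / 256 * n_levels) + 1, n_levels), nrow(g),
              ncol(g))
  offsets <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  har <- rowMeans(vapply(offsets, function(o) {
    haralick_one(glcm_one(q, n_levels, o[1], o[2]))
  }, numeric(13)))
  c(har, hu_moments(g / 255))
}
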