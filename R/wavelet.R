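#' Wavelet analysis parameters
#'
#' Parameters for the time-frequency machinery: the generalized Morse
#' wavelet used for the scalogram and its inverse (symmetry parameter
#' gamma_m and time-bandwidth product P^2 = beta_m * gamma_m; the defaults
#' 3 and 60 give beta_m = 20), the scale-grid density, and the Morlet
#' center frequency omega0 used for wavelet coherence.
#'
#' @param morse_symmetry Morse symmetry parameter gamma_m (> 0, default 3).
#' @param morse_time_bandwidth Time-bandwidth product P^2 (default 60);
#'   must be at least `morse_symmetry` so the peak frequency is defined.
#' @param voices_per_octave Scale-grid density (>= 4, default 12).
#' @param morlet_omega0 Morlet center frequency (default 6).
#' @return Object of class `wavelet_params`.
#' @export
wavelet_params <- function(morse_symmetry = 3, morse_time_bandwidth = 60,
                           voices_per_octave = 12, morlet_omega0 = 6) {
  stopifnot(morse_symmetry > 0,
            morse_time_bandwidth >= morse_symmetry,
            voices_per_octave >= 4, morlet_omega0 > 0)
  structure(list(morse_symmetry = morse_symmetry,
                 morse_time_bandwidth = morse_time_bandwidth,
                 voices_per_octave = voices_per_octave,
                 morlet_omega0 = morlet_omega0),
            class = "wavelet_params")
}

# logarithmic frequency grid from fs/2 down to 2 cycles per record
.freq_grid <- function(n, fs, nv) {
  fmax <- fs / 2
  fmin <- 2 * fs / n
  k <- 0:ceiling(nv * log2(fmax / fmin))
  fmax * 2^(-k / nv)
}

# Morse peak angular frequency and amplitude constant (peak value 2)
.morse_const <- function(gam, bet) {
  wp <- (bet / gam)^(1 / gam)
  list(wp = wp, a = 2 / (wp^bet * exp(-wp^gam)))
}

#' Continuous wavelet transform with the analytic generalized Morse wavelet
#'
#' Frequency-domain implementation: the mean-removed signal is zero-padded
#' to the next power of two at least twice its length, and each scale row
#' is the inverse FFT of the spectrum multiplied by the (analytic,
#' positive-frequency) Morse window. Amplitude convention: a unit-amplitude
#' sinusoid yields coefficients of magnitude ~1 at its scale. The signal
#' mean is stored and restored by [icwt()].
#'
#' @param x Finite numeric signal, length >= 32, no NaN (gap-fill motion
#'   traces first).
#' @param fs Sampling rate in Hz.
#' @param params A [wavelet_params()].
#' @return Object of class `scalogram`: complex `coefficients`
#'   (scales x time, frequencies strictly decreasing with row index),
#'   `frequencies` (Hz), `scales` (samples), `coi` (cone-of-influence
#'   boundary frequency per sample, Hz), `fs`, `params`, `signal_mean`.
#' @export
cwt_morse <- function(x, fs, params = wavelet_params()) {
  stopifnot(is.numeric(x), fs > 0, inherits(params, "wavelet_params"))
  if (length(x) < 32) stop("signal shorter than 32 samples")
  if (!all(is.finite(x))) stop("signal contains NaN/Inf; gap-fill first")
  n <- length(x)
  gam <- params$morse_symmetry
  bet <- params$morse_time_bandwidth / gam
  mc <- .morse_const(gam, bet)
  freqs <- .freq_grid(n, fs, params$voices_per_octave)
  scales <- mc$wp / (2 * pi * freqs / fs)
  np <- 2^ceiling(log2(2 * n))
  xh <- stats::fft(c(x - mean(x), rep(0, np - n)))
  om <- 2 * pi * (0:(np - 1)) / np
  pos <- 2:(np / 2 + 1)
  # filter bank: np x nscales, positive frequencies only (analytic wavelet)
  U <- outer(om[pos], scales)
  Psi <- matrix(0, np, length(scales))
  Psi[pos, ] <- mc$a * U^bet * exp(-U^gam)
  W <- stats::mvfft(Psi * xh, inverse = TRUE)[seq_len(n), , drop = FALSE] / np
  # cone of influence: two Gaussian-equivalent time spreads from the edge
  d <- pmax(pmin(seq_len(n) - 1, n - seq_len(n)), 1)
  coi <- pmin(fs * sqrt(bet * gam) / (pi * d), fs / 2)
  structure(list(coefficients = t(W), frequencies = freqs, scales = scales,
                 fs = fs, coi = coi, params = params, signal_mean = mean(x),
                 n = n),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf(
    "Morse scalogram: %d scales x %d samples, %.4g-%.4g Hz @ %g Hz\n",
    nrow(x$coefficients), ncol(x$coefficients),
    min(x$frequencies), max(x$frequencies), x$fs))
  invisible(x)
}

#' @export
plot.scalogram <- function(x, main = "CWT magnitude", ...) {
  t <- (seq_len(ncol(x$coefficients)) - 1) / x$fs
  graphics::image(t, rev(log2(x$frequencies)),
                  t(abs(x$coefficients)[rev(seq_along(x$frequencies)), ]),
                  xlab = "time (s)", ylab = "log2 frequency (Hz)",
                  main = main, useRaster = TRUE, ...)
  graphics::lines(t, log2(x$coi), lty = 2)
  invisible(x)
}

#' Inverse continuous wavelet transform with coefficient exclusion
#'
#' Single-integral reconstruction: the real parts of the coefficients are
#' summed over the logarithmic scale grid and rescaled by the closed-form
#' admissibility constant of the Morse window, after zeroing any
#' coefficients flagged in `mask`. The stored signal mean is added back.
#'
#' @param scalogram A [cwt_morse()] result.
#' @param mask Optional logical matrix, same dimensions as the
#'   coefficients; `TRUE` cells are excluded from the reconstruction.
#' @return Numeric signal of the original length.
#' @export
icwt <- function(scalogram, mask = NULL) {
  stopifnot(inherits(scalogram, "scalogram"))
  W <- scalogram$coefficients
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(W)))
      stop("mask must be a logical matrix matching the coefficient grid")
    W[mask] <- 0 + 0i
  }
  p <- scalogram$params
  gam <- p$morse_symmetry
  bet <- p$morse_time_bandwidth / gam
  mc <- .morse_const(gam, bet)
  Cpsi <- mc$a * base::gamma(bet / gam) / gam     # int psi_hat(u)/u du
  (2 * log(2) / (p$voices_per_octave * Cpsi)) * colSums(Re(W)) +
    scalogram$signal_mean
}

# Morlet filter bank CWT on a given frequency grid (analytic, peak 2)
.cwt_morlet <- function(x, fs, freqs, w0) {
  n <- length(x)
  np <- 2^ceiling(log2(2 * n))
  xh <- stats::fft(c(x - mean(x), rep(0, np - n)))
  om <- 2 * pi * (0:(np - 1)) / np
  pos <- 2:(np / 2 + 1)
  scales <- w0 / (2 * pi * freqs / fs)
  Psi <- matrix(0, np, length(scales))
  Psi[pos, ] <- 2 * exp(-sweep(outer(om[pos], scales), 2, w0)^2 / 2)
  W <- stats::mvfft(Psi * xh, inverse = TRUE)[seq_len(n), , drop = FALSE] / np
  list(W = t(W), scales = scales)
}

# Gaussian time smoothing (SD = scale, per row) via FFT; M complex or real
.smooth_time <- function(M, scales) {
  n <- ncol(M)
  np <- 2^ceiling(log2(2 * n))
  om <- 2 * pi * c(0:(np / 2), -(np / 2 - 1):-1) / np
  Mp <- cbind(M, matrix(0, nrow(M), np - n))
  Fh <- t(stats::mvfft(t(Mp)))
  G <- exp(-0.5 * outer(scales, om)^2)
  t(stats::mvfft(t(Fh * G), inverse = TRUE))[, seq_len(n), drop = FALSE] / np
}

# boxcar smoothing across scale rows, edge-renormalized
.smooth_scale <- function(M, halfw) {
  J <- nrow(M)
  out <- M
  for (j in seq_len(J)) {
    lo <- max(1, j - halfw); hi <- min(J, j + halfw)
    out[j, ] <- colMeans(M[lo:hi, , drop = FALSE])
  }
  out
}

#' Morlet wavelet coherence
#'
#' Magnitude-squared wavelet coherence between two equal-length signals,
#' computed with the analytic Morlet wavelet and the standard smoothing
#' convention: a Gaussian filter in time whose width is proportional to
#' scale, then a boxcar across about 0.6 octave of scales. The map is
#' evaluated on the same logarithmic frequency grid as [cwt_morse()] at
#' equal `voices_per_octave`, so coherence and scalogram cells correspond
#' one-to-one.
#'
#' @param x,y Finite numeric signals of equal length and nonzero variance.
#' @param fs Sampling rate in Hz.
#' @param params A [wavelet_params()].
#' @return Object of class `coherence_map` with `values` (scales x time in
#'   `[0, 1]`), `frequencies` (Hz) and `fs`.
#' @export
wcoh_morlet <- function(x, y, fs, params = wavelet_params()) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input")
  freqs <- .freq_grid(length(x), fs, params$voices_per_octave)
  Wx <- .cwt_morlet(x, fs, freqs, params$morlet_omega0)
  Wy <- .cwt_morlet(y, fs, freqs, params$morlet_omega0)
  inv_s <- 1 / Wx$scales
  halfw <- max(1L, round(0.3 * params$voices_per_octave))
  Sxx <- .smooth_scale(Re(.smooth_time(abs(Wx$W)^2 * inv_s, Wx$scales)), halfw)
  Syy <- .smooth_scale(Re(.smooth_time(abs(Wy$W)^2 * inv_s, Wx$scales)), halfw)
  Sxy <- .smooth_scale(.smooth_time(Wx$W * Conj(Wy$W) * inv_s, Wx$scales), halfw)
  coh <- abs(Sxy)^2 / (Sxx * Syy)
  coh[!is.finite(coh)] <- 0
  structure(list(values = pmin(pmax(Re(coh), 0), 1), frequencies = freqs,
                 fs = fs, params = params),
            class = "coherence_map")
}

#' @export
print.coherence_map <- function(x, ...) {
  cat(sprintf("Wavelet coherence: %d scales x %d samples, median %.3f\n",
              nrow(x$values), ncol(x$values), stats::median(x$values)))
  invisible(x)
}

#' @export
plot.coherence_map <- function(x, main = "Wavelet coherence", ...) {
  t <- (seq_len(ncol(x$values)) - 1) / x$fs
  graphics::image(t, rev(log2(x$frequencies)),
                  t(x$values[rev(seq_along(x$frequencies)), ]),
                  zlim = c(0, 1), xlab = "time (s)",
                  ylab = "log2 frequency (Hz)", main = main,
                  useRaster = TRUE, ...)
  invisible(x)
}
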