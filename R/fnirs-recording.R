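#' Multichannel fNIRS recording
#'
#' Thin container for a channels-by-time matrix with its sampling rate,
#' channel labels, a channel-to-detector map (each fNIRS channel is a
#' source-detector pair; motion traces are tracked per detector), and a
#' chromophore label per channel (`"O2Hb"`, `"HHb"` or `"OD"`).
#'
#' @param data Numeric matrix, channels x time.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one per channel (default
#'   `ch1..chN`).
#' @param detector Character or integer vector mapping each channel to a
#'   detector id (default: channels split evenly over two detectors, the
#'   8-channel / 2-detector prefrontal montage).
#' @param chromophore Character vector per channel (default `"O2Hb"`).
#' @return Object of class `fnirs_recording`.
#' @export
fnirs_recording <- function(data, fs, channel_labels = NULL, detector = NULL,
                            chromophore = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), fs > 0, all(is.finite(data)))
  nc <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nc))
  if (is.null(detector))
    detector <- paste0("det", rep(1:2, each = ceiling(nc / 2), length.out = nc))
  if (is.null(chromophore)) chromophore <- rep("O2Hb", nc)
  stopifnot(length(channel_labels) == nc, length(detector) == nc,
            length(chromophore) == nc)
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 detector = as.character(detector), chromophore = chromophore),
            class = "fnirs_recording")
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf("fNIRS recording: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  detectors:", paste(unique(x$detector), collapse = ", "), "\n")
  cat("  chromophores:", paste(unique(x$chromophore), collapse = ", "), "\n")
  invisible(x)
}

#' Synthetic resting-state fNIRS recording
#'
#' Each channel is a sum of sinusoids at the cardiac (~1.1 Hz), respiratory
#' (~0.25 Hz) and Mayer-wave (~0.1 Hz) bands with independent random phases
#' per channel, a slow drift, and white noise. Deterministic given `seed`.
#'
#' @param fs Sampling rate in Hz; must be at least 2.5 Hz so the cardiac
#'   band is representable.
#' @param duration Recording duration in seconds (at least 60 s, so the
#'   band structure is spectrally resolvable).
#' @param n_channels Number of channels (default 8).
#' @param amplitudes Named numeric vector of component amplitudes in signal
#'   units: `cardiac`, `respiratory`, `mayer`, `drift`, `noise`.
#' @param band_centers Named numeric vector of band center frequencies (Hz).
#' @param seed Integer seed.
#' @return An [fnirs_recording()].
#' @export
synth_resting_fnirs <- function(fs, duration, n_channels = 8,
                                amplitudes = c(cardiac = 0.3, respiratory = 0.2,
                                               mayer = 0.4, drift = 0.3,
                                               noise = 0.1),
                                band_centers = c(cardiac = 1.1,
                                                 respiratory = 0.25,
                                                 mayer = 0.1),
                                seed = 1L) {
  if (fs < 2.5) stop("fs < 2.5 Hz: cardiac band unrepresentable")
  if (duration < 60) stop("duration must be at least 60 s")
  stopifnot(n_channels >= 1)
  a <- amplitudes[c("cardiac", "respiratory", "mayer", "drift", "noise")]
  if (anyNA(a)) stop("amplitudes must name cardiac, respiratory, mayer, drift, noise")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dat <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    ph <- stats::runif(4, 0, 2 * pi)
    x <- a[["cardiac"]] * sin(2 * pi * band_centers[["cardiac"]] * t + ph[1]) +
      a[["respiratory"]] * sin(2 * pi * band_centers[["respiratory"]] * t + ph[2]) +
      a[["mayer"]] * sin(2 * pi * band_centers[["mayer"]] * t + ph[3]) +
      a[["drift"]] * sin(2 * pi * 0.008 * t + ph[4]) +
      stats::rnorm(n, 0, a[["noise"]])
    dat[ch, ] <- x
  }
  fnirs_recording(dat, fs)
}

# Save/restore .Random.seed so seeded generators do not disturb the caller's
# RNG stream (generators are pure functions of their seed).
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
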