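#' Block-design experiment paradigm
#'
#' Describes a block paradigm as a set of task-block onsets with a common
#' block duration, over a fixed total recording duration. Used to build the
#' boxcar regressor and to inject simulated activations.
#'
#' @param block_onsets Numeric vector of block onset times in seconds,
#'   strictly increasing. May be empty (a rest-only paradigm).
#' @param block_duration Duration of each task block in seconds.
#' @param total_duration Total recording duration in seconds.
#' @param amplitude Boxcar amplitude in signal units (default 1).
#' @return An object of class `paradigm`.
#' @examples
#' p <- paradigm(seq(20, 260, by = 40), 20, 300)
#' @export
paradigm <- function(block_onsets, block_duration, total_duration, amplitude = 1) {
  stopifnot(is.numeric(block_onsets), block_duration > 0, total_duration > 0,
            amplitude >= 0)
  if (length(block_onsets)) {
    if (is.unsorted(block_onsets, strictly = TRUE))
      stop("block onsets must be strictly increasing")
    if (any(block_onsets < 0))
      stop("block onsets must be non-negative")
    if (max(block_onsets) + block_duration > total_duration + 1e-9)
      stop("a block extends past total_duration")
    if (length(block_onsets) > 1 &&
        any(diff(block_onsets) < block_duration - 1e-9))
      stop("overlapping blocks")
  }
  structure(list(block_onsets = as.numeric(block_onsets),
                 block_duration = block_duration,
                 total_duration = total_duration,
                 amplitude = amplitude),
            class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf("Block paradigm: %d block(s) of %g s over %g s (amplitude %g)\n",
              length(x$block_onsets), x$block_duration, x$total_duration,
              x$amplitude))
  invisible(x)
}

#' Boxcar time series for a block paradigm
#'
#' Samples the paradigm on a uniform grid: `amplitude` inside task blocks
#' (half-open intervals `[onset, onset + duration)`), 0 elsewhere.
#'
#' @param paradigm A [paradigm()] object.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length `round(total_duration * fs)`.
#' @export
make_boxcar <- function(paradigm, fs) {
  stopifnot(inherits(paradigm, "paradigm"), fs > 0)
  n <- round(paradigm$total_duration * fs)
  b <- numeric(n)
  for (o in paradigm$block_onsets) {
    i0 <- floor(o * fs) + 1L
    i1 <- min(n, floor((o + paradigm$block_duration) * fs))
    if (i1 >= i0) b[i0:i1] <- paradigm$amplitude
  }
  b
}

#' Canonical double-gamma haemodynamic response kernel
#'
#' SPM-style double-gamma HRF: a positive response lobe peaking around
#' `peak_delay` seconds followed by a smaller undershoot around
#' `undershoot_delay` seconds, normalized to a maximum of exactly 1.
#'
#' @param fs Sampling rate in Hz.
#' @param peak_delay,undershoot_delay Gamma shape delays in seconds
#'   (defaults 6 and 16).
#' @param peak_disp,undershoot_disp Dispersions (defaults 1).
#' @param ratio Undershoot-to-peak ratio (default 1/6).
#' @param duration Kernel support in seconds (default 32; the kernel has
#'   decayed below 1% of its peak by then).
#' @return Numeric kernel sampled at `fs`, unit peak.
#' @export
canonical_hrf <- function(fs, peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1,
                          ratio = 1 / 6, duration = 32) {
  stopifnot(fs > 0, peak_delay > 0, undershoot_delay > 0, ratio >= 0)
  tt <- seq(0, duration, by = 1 / fs)
  h <- stats::dgamma(tt, shape = peak_delay / peak_disp, rate = 1 / peak_disp) -
    ratio * stats::dgamma(tt, shape = undershoot_delay / undershoot_disp,
                          rate = 1 / undershoot_disp)
  h / max(h)
}

#' Unit-peak activation regressor for a block paradigm
#'
#' Causal convolution of the paradigm boxcar with an HRF kernel, rescaled to
#' unit peak so that activation amplitudes are expressed directly in signal
#' units. This is the GLM regressor used throughout the benchmark.
#'
#' @param paradigm A [paradigm()] object (its `amplitude` is ignored here;
#'   the result is unit-peak).
#' @param fs Sampling rate in Hz.
#' @param hrf Optional HRF kernel at `fs`; default [canonical_hrf()].
#' @return Numeric vector, same length as the boxcar, max value 1 (all-zero
#'   for a paradigm with no blocks).
#' @export
activation_regressor <- function(paradigm, fs, hrf = canonical_hrf(fs)) {
  b <- make_boxcar(paradigm, fs)
  if (all(b == 0)) return(b)
  # exact causal FIR convolution (no FFT round-off before the first onset)
  k <- length(hrf)
  r <- stats::filter(c(rep(0, k - 1), b), hrf, method = "convolution",
                     sides = 1)[k:(k + length(b) - 1)]
  as.numeric(r) / max(r)
}

#' Add a simulated block activation to a recording
#'
#' Adds `amplitude * activation_regressor(...)` to every channel. The
#' regressor is causal: no channel changes before the first block onset.
#'
#' @param recording An [fnirs_recording()].
#' @param paradigm A [paradigm()].
#' @param hrf HRF kernel at the recording's sampling rate.
#' @param amplitude Activation amplitude in signal units.
#' @return A list with elements `recording` (activation added), `activation`
#'   (the added series), `regressor` (unit-peak regressor), and `rest_mask`
#'   (logical, `TRUE` where the boxcar is 0).
#' @export
add_activation <- function(recording, paradigm, hrf = NULL, amplitude = 1) {
  stopifnot(inherits(recording, "fnirs_recording"))
  if (is.null(hrf)) hrf <- canonical_hrf(recording$fs)
  reg <- activation_regressor(paradigm, recording$fs, hrf)
  n <- ncol(recording$data)
  if (length(reg) != n)
    stop("paradigm duration does not match recording length")
  act <- amplitude * reg
  out <- recording
  out$data <- recording$data + matrix(act, nrow(recording$data), n, byrow = TRUE)
  list(recording = out,
       activation = act,
       regressor = reg,
       rest_mask = make_boxcar(paradigm, recording$fs) == 0)
}
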