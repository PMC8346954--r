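#' Correction configuration
#'
#' Settings of the time-frequency exclusion procedure: the shared threshold
#' `T` applied to the globally max-normalized motion scalogram magnitude
#' and to the wavelet coherence, and the rule combining the two exceedance
#' maps. The default threshold 0.6 is the value retained after sweeping
#' `{0.4, 0.5, 0.6, 0.7, 0.8}` on the simulation benchmark (it maximizes
#' SNR); the intersection rule masks a cell only when it both carries
#' motion energy and coheres with the signal, which protects the
#' haemodynamic band.
#'
#' @param threshold Threshold `T` in `(0, 1]` (default 0.6).
#' @param combine_rule `"intersection"` (default) or `"union"`.
#' @param tested_thresholds Candidate thresholds for [threshold_sweep()]
#'   (default `c(0.4, 0.5, 0.6, 0.7, 0.8)`).
#' @return Object of class `correction_config`.
#' @export
correction_config <- function(threshold = 0.6,
                              combine_rule = c("intersection", "union"),
                              tested_thresholds = c(0.4, 0.5, 0.6, 0.7, 0.8)) {
  stopifnot(threshold > 0)
  combine_rule <- match.arg(combine_rule)
  structure(list(threshold = threshold, combine_rule = combine_rule,
                 tested_thresholds = tested_thresholds),
            class = "correction_config")
}

#' Build the time-frequency exclusion mask
#'
#' Normalizes the motion scalogram magnitude by its global maximum,
#' `M(s,t) = |W_motion|(s,t) / max|W_motion|`, and marks a cell for
#' exclusion when `M > T` and (intersection) / or (union) the
#' signal-motion coherence exceeds `T`. An all-zero motion scalogram gives
#' an empty mask: no motion, nothing to exclude. With `T > 1` the mask is
#' empty regardless of input, since both maps are bounded by 1.
#'
#' @param motion_scalogram [cwt_morse()] of the motion trace.
#' @param coherence [wcoh_morlet()] of signal and motion, on the same grid.
#' @param config A [correction_config()].
#' @return Logical matrix (scales x time), `TRUE` where excluded.
#' @export
build_mask <- function(motion_scalogram, coherence,
                       config = correction_config()) {
  stopifnot(inherits(motion_scalogram, "scalogram"),
            inherits(coherence, "coherence_map"))
  A <- abs(motion_scalogram$coefficients)
  if (!identical(dim(A), dim(coherence$values)) ||
      max(abs(motion_scalogram$frequencies - coherence$frequencies)) > 1e-9)
    stop("scalogram and coherence grids are not congruent")
  mx <- max(A)
  if (mx == 0) return(matrix(FALSE, nrow(A), ncol(A)))
  M <- A / mx
  Tt <- config$threshold
  if (config$combine_rule == "intersection")
    (M > Tt) & (coherence$values > Tt)
  else
    (M > Tt) | (coherence$values > Tt)
}

#' Correct a single fNIRS channel against a motion trace
#'
#' The channel's Morse scalogram is masked by [build_mask()] -- built from
#' the motion trace's scalogram and the channel-motion wavelet coherence --
#' and the masked (motion-related) content, reconstructed by [icwt()], is
#' subtracted from the signal. Signal content the transform cannot
#' represent (sub-band drift, the broadband noise floor) is therefore
#' preserved, and with zero motion the mask is empty and the output equals
#' the input exactly.
#'
#' @param signal Numeric channel time series.
#' @param motion A [motion_trace()] (or numeric vector) of the same length
#'   and rate; gaps must already be filled ([resultant_motion()] does).
#' @param config A [correction_config()].
#' @param params A [wavelet_params()].
#' @param motion_scalogram Optional precomputed [cwt_morse()] of the motion
#'   values (channels sharing a detector share it).
#' @return List: `corrected` signal, `mask`, `mask_occupancy` (fraction of
#'   cells excluded), `coherence`.
#' @export
correct_channel <- function(signal, motion, config = correction_config(),
                            params = wavelet_params(),
                            motion_scalogram = NULL) {
  mvals <- if (inherits(motion, "motion_trace")) motion$values else motion
  fs <- if (inherits(motion, "motion_trace")) motion$fs else NULL
  if (length(mvals) != length(signal))
    stop("signal and motion lengths differ; resample the motion trace first")
  if (!all(is.finite(mvals))) stop("motion trace contains gaps; fill first")
  if (is.null(motion_scalogram)) {
    if (is.null(fs)) stop("motion must be a motion_trace or fs known via motion_scalogram")
    motion_scalogram <- cwt_morse(mvals, fs, params)
  }
  fs <- motion_scalogram$fs
  sig_sc <- cwt_morse(signal, fs, params)
  coh <- if (stats::sd(mvals) == 0) {
    # constant motion: zero coherence everywhere, empty mask either way
    structure(list(values = matrix(0, nrow(sig_sc$coefficients),
                                   ncol(sig_sc$coefficients)),
                   frequencies = sig_sc$frequencies, fs = fs,
                   params = params),
              class = "coherence_map")
  } else wcoh_morlet(signal, mvals, fs, params)
  mask <- build_mask(motion_scalogram, coh, config)
  # subtract the reconstruction of the excluded cells only: content the
  # transform cannot represent (very slow drift, broadband noise floor,
  # boundary residue) passes through untouched, and an empty mask is an
  # exact identity
  excluded <- icwt(sig_sc, !mask) - sig_sc$signal_mean
  list(corrected = signal - excluded, mask = mask,
       mask_occupancy = mean(mask), coherence = coh)
}

#' Correct a whole fNIRS recording
#'
#' Applies [correct_channel()] to every channel, using the motion trace of
#' the detector that channel maps to. Channels sharing a detector share one
#' motion scalogram; the coherence, and hence the mask, is channel-specific.
#'
#' @param recording An [fnirs_recording()].
#' @param traces Named list of [motion_trace()] objects, one per detector
#'   id appearing in `recording$detector`.
#' @param config A [correction_config()].
#' @param params A [wavelet_params()].
#' @param store_masks Keep the per-channel masks in the result
#'   (default `FALSE`; they are large).
#' @return Object of class `correction_result`: `corrected` (an
#'   [fnirs_recording()]), `mask_occupancy` per channel,
#'   `n_motion_scalograms`, `config`, and optionally `masks`.
#' @export
correct_recording <- function(recording, traces,
                              config = correction_config(),
                              params = wavelet_params(),
                              store_masks = FALSE) {
  stopifnot(inherits(recording, "fnirs_recording"), is.list(traces))
  dets <- unique(recording$detector)
  missing_det <- setdiff(dets, names(traces))
  if (length(missing_det)) {
    ch <- recording$channel_labels[recording$detector %in% missing_det]
    stop("no motion trace for detector(s) ", paste(missing_det, collapse = ", "),
         " (channels ", paste(ch, collapse = ", "), ")")
  }
  n <- ncol(recording$data)
  msc <- list()
  for (d in dets) {
    tr <- traces[[d]]
    stopifnot(inherits(tr, "motion_trace"))
    if (length(tr$values) != n || abs(tr$fs - recording$fs) > 1e-9)
      stop("trace for detector ", d, " not aligned with recording")
    msc[[d]] <- cwt_morse(tr$values, recording$fs, params)
  }
  out <- recording
  occ <- numeric(nrow(recording$data))
  masks <- if (store_masks) vector("list", nrow(recording$data)) else NULL
  for (ch in seq_len(nrow(recording$data))) {
    d <- recording$detector[ch]
    res <- correct_channel(recording$data[ch, ], traces[[d]], config, params,
                           motion_scalogram = msc[[d]])
    out$data[ch, ] <- res$corrected
    occ[ch] <- res$mask_occupancy
    if (store_masks) masks[[ch]] <- res$mask
  }
  names(occ) <- recording$channel_labels
  structure(list(corrected = out, mask_occupancy = occ,
                 n_motion_scalograms = length(dets), config = config,
                 params = params, masks = masks),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf(
    "Motion correction: %d channel(s), %d motion scalogram(s), T = %g (%s)\n",
    nrow(x$corrected$data), x$n_motion_scalograms, x$config$threshold,
    x$config$combine_rule))
  cat(sprintf("  mask occupancy: %.2f%% - %.2f%% (median %.2f%%)\n",
              100 * min(x$mask_occupancy), 100 * max(x$mask_occupancy),
              100 * stats::median(x$mask_occupancy)))
  invisible(x)
}

#' @export
summary.correction_result <- function(object, ...) {
  data.frame(channel = object$corrected$channel_labels,
             detector = object$corrected$detector,
             mask_occupancy = as.numeric(object$mask_occupancy),
             row.names = NULL)
}

#' @export
plot.correction_result <- function(x, channel = 1, original = NULL, ...) {
  t <- (seq_len(ncol(x$corrected$data)) - 1) / x$corrected$fs
  graphics::plot(t, x$corrected$data[channel, ], type = "l",
                 xlab = "time (s)", ylab = "signal",
                 main = paste("corrected:", x$corrected$channel_labels[channel]),
                 ...)
  if (!is.null(original))
    graphics::lines(t, original, col = "grey60")
  invisible(x)
}
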