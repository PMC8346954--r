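#' Wavelet-IQR artifact correction (Molavi-Dumont style)
#'
#' Shift-invariant a-trous (starlet) decomposition of the signal into
#' detail planes plus a coarse residual; at each level, detail coefficients
#' whose magnitude falls outside `iqr_factor` interquartile ranges of the
#' level's quartiles are assumed artifactual and zeroed; the signal is
#' rebuilt by summation. The decomposition is additive
#' (`x = approx + sum(details)` exactly), so an infinite factor returns
#' the input unchanged.
#'
#' @param signal Finite numeric vector.
#' @param iqr_factor Outlier band half-width in IQR units (default 1.5).
#' @param n_levels Decomposition depth (default 6).
#' @return Corrected signal, same length.
#' @export
wavelet_iqr_correct <- function(signal, iqr_factor = 1.5, n_levels = 6L) {
  stopifnot(all(is.finite(signal)), iqr_factor > 0, n_levels >= 1)
  dec <- .atrous_decompose(signal, n_levels)
  out <- dec$approx
  for (j in seq_len(n_levels)) {
    d <- dec$details[, j]
    if (is.finite(iqr_factor)) {
      q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      d[d < q[1] - iqr_factor * iqr | d > q[2] + iqr_factor * iqr] <- 0
    }
    out <- out + d
  }
  out
}

# a-trous decomposition with the B3-spline kernel; details are differences
# of successive approximations, so reconstruction by summation is exact
.atrous_decompose <- function(x, n_levels) {
  n <- length(x)
  k <- c(1, 4, 6, 4, 1) / 16
  details <- matrix(0, n, n_levels)
  a <- x
  for (j in seq_len(n_levels)) {
    step <- 2^(j - 1)
    idx <- function(i) pmin(pmax(i, 1L), n)
    a_next <- k[1] * a[idx(seq_len(n) - 2L * step)] +
      k[2] * a[idx(seq_len(n) - step)] +
      k[3] * a +
      k[4] * a[idx(seq_len(n) + step)] +
      k[5] * a[idx(seq_len(n) + 2L * step)]
    details[, j] <- a - a_next
    a <- a_next
  }
  list(details = details, approx = a)
}

#' PCA-based artifact correction
#'
#' Removes the projection of the multichannel data onto its top-variance
#' principal directions; movement artifacts shared across channels load on
#' the leading components.
#'
#' @param recording An [fnirs_recording()] (or channels x time matrix)
#'   with at least 2 channels.
#' @param n_components Number of components to remove; must be smaller
#'   than the number of channels. 0 is the identity.
#' @return List: `recording` (corrected, same class as input),
#'   `removed_variance` (fraction of total variance removed, equal to the
#'   share of the top eigenvalues).
#' @export
pca_correct <- function(recording, n_components = 1L) {
  is_rec <- inherits(recording, "fnirs_recording")
  X <- if (is_rec) recording$data else as.matrix(recording)
  nc <- nrow(X)
  if (nc < 2) stop("need at least 2 channels")
  if (n_components >= nc) stop("n_components must be < number of channels")
  if (n_components == 0) {
    out <- recording
    return(list(recording = out, removed_variance = 0))
  }
  Xt <- t(X)                              # time x channels
  mu <- colMeans(Xt)
  Xc <- sweep(Xt, 2, mu)
  sv <- svd(Xc)
  idx <- seq_len(n_components)
  recon <- sv$u[, idx, drop = FALSE] %*%
    (sv$d[idx] * t(sv$v[, idx, drop = FALSE]))
  Yc <- Xc - recon
  Y <- t(sweep(Yc, 2, mu, "+"))
  removed <- sum(sv$d[idx]^2) / sum(sv$d^2)
  if (is_rec) {
    out <- recording
    out$data <- Y
    dimnames(out$data) <- dimnames(X)
  } else out <- Y
  list(recording = out, removed_variance = removed)
}

#' Spline-based artifact correction (MARA style)
#'
#' Within each externally flagged artifact segment, a smoothing spline is
#' fitted and subtracted, and the segment is re-leveled to its own first
#' spline value; the remainder of the signal after the segment is shifted
#' so the series stays continuous at both segment boundaries. This removes
#' baseline excursions (including persistent steps) inside the flagged
#' spans while leaving everything outside untouched up to the continuity
#' shift.
#'
#' @param signal Finite numeric vector.
#' @param segments List of integer pairs `c(start, end)` (1-based sample
#'   indices, inclusive, non-overlapping).
#' @param spar Smoothing parameter passed to [stats::smooth.spline()]
#'   (default 0.5).
#' @return Corrected signal, same length.
#' @export
spline_mara_correct <- function(signal, segments, spar = 0.5) {
  stopifnot(all(is.finite(signal)))
  if (!length(segments)) return(signal)
  segs <- do.call(rbind, lapply(segments, function(s) {
    stopifnot(length(s) == 2, s[1] >= 1, s[2] <= length(signal), s[1] <= s[2])
    as.integer(s)
  }))
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  if (nrow(segs) > 1 && any(segs[-1, 1] <= segs[-nrow(segs), 2]))
    stop("overlapping segments")
  x <- signal
  n <- length(x)
  for (i in seq_len(nrow(segs))) {
    a <- segs[i, 1]; b <- segs[i, 2]
    seg <- x[a:b]
    if (stats::sd(seg) == 0 || b - a < 8) next
    sp <- stats::smooth.spline(a:b, seg, spar = spar)
    fit <- stats::predict(sp, a:b)$y
    x[a:b] <- seg - fit + fit[1]
    if (b < n) x[(b + 1):n] <- x[(b + 1):n] + fit[1] - fit[length(fit)]
  }
  x
}

#' Flag artifact segments from a motion trace
#'
#' Marks spans where the displacement exceeds a quantile of the trace,
#' pads them, and merges adjacent spans -- the segment input expected by
#' [spline_mara_correct()].
#'
#' @param motion A [motion_trace()] or numeric vector.
#' @param q Exceedance quantile (default 0.90).
#' @param pad Padding added on both sides, seconds (default 1).
#' @param fs Sampling rate, required when `motion` is a bare vector.
#' @return List of `c(start, end)` integer pairs (possibly empty).
#' @export
motion_segments <- function(motion, q = 0.90, pad = 1, fs = NULL) {
  v <- if (inherits(motion, "motion_trace")) motion$values else motion
  if (inherits(motion, "motion_trace")) fs <- motion$fs
  stopifnot(!is.null(fs))
  thr <- stats::quantile(v, q, names = FALSE)
  hot <- v > thr
  if (!any(hot)) return(list())
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- cbind(starts[r$values], ends[r$values])
  w <- round(pad * fs)
  segs[, 1] <- pmax(1, segs[, 1] - w)
  segs[, 2] <- pmin(length(v), segs[, 2] + w)
  # merge overlaps created by padding
  merged <- list(segs[1, ])
  for (i in seq_len(nrow(segs))[-1]) {
    last <- merged[[length(merged)]]
    if (segs[i, 1] <= last[2] + 1)
      merged[[length(merged)]] <- c(last[1], max(last[2], segs[i, 2]))
    else merged[[length(merged) + 1]] <- segs[i, ]
  }
  merged
}

#' Correlation-based signal improvement (CBSI)
#'
#' Enforces the physiological anticorrelation of oxy- and deoxyhemoglobin:
#' with `alpha = sd(hbo)/sd(hhb)`, returns
#' `hbo0 = (hbo - alpha * hhb) / 2` and `hhb0 = -hbo0 / alpha`, so the
#' corrected pair is perfectly anticorrelated and common-mode (motion)
#' content cancels.
#'
#' @param hbo,hhb Equal-length numeric vectors with nonzero variance.
#' @return List: `hbo`, `hhb` (corrected), `alpha`.
#' @export
cbsi_correct <- function(hbo, hhb) {
  stopifnot(length(hbo) == length(hhb), all(is.finite(hbo)),
            all(is.finite(hhb)))
  s1 <- stats::sd(hbo); s2 <- stats::sd(hhb)
  if (s1 == 0 || s2 == 0) stop("zero-variance input")
  alpha <- s1 / s2
  hbo0 <- (hbo - alpha * hhb) / 2
  list(hbo = hbo0, hhb = -hbo0 / alpha, alpha = alpha)
}
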