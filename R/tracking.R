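#' Otsu threshold segmentation of a thermal frame
#'
#' Finds the temperature threshold maximizing the between-class variance
#' over a 256-bin histogram of the frame's range, and returns the skin mask
#' (pixels strictly above threshold). On a facial thermogram the skin is
#' warmer than the background, so the upper class is the soft tissue.
#'
#' @param frame Numeric matrix of temperatures; must contain at least two
#'   distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return List with `threshold` (degrees C, a bin edge) and `skin_mask`
#'   (logical matrix, `TRUE` above threshold).
#' @export
otsu_segment <- function(frame, n_bins = 256L) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  lo <- min(frame); hi <- max(frame)
  if (hi <= lo) stop("constant frame: no separation possible")
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(frame, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  p <- cnt / sum(cnt)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)                        # class 0 = bins 1..k
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  # between-class variance for a split after bin k (k = 1..n_bins-1)
  k <- seq_len(n_bins - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu_t * w0[k][valid] - mu0[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  kbest <- which.max(bcv)
  thr <- breaks[kbest + 1L]
  list(threshold = thr, skin_mask = frame > thr)
}

#' Gaussian pyramid decimation
#'
#' Each level applies a separable 5-tap binomial low-pass filter
#' (`[1,4,6,4,1]/16`, reflecting at the borders) and then keeps every second
#' pixel per axis, so a 240 x 320 frame becomes 120 x 160 at level 1.
#'
#' @param image Numeric matrix.
#' @param level Non-negative integer; level 0 is the identity.
#' @return Matrix of dimensions `ceiling(dim(image) / 2^level)`.
#' @export
gaussian_pyramid <- function(image, level) {
  stopifnot(is.matrix(image), level >= 0, level == round(level))
  out <- image
  for (l in seq_len(level)) {
    if (any(dim(out) < 2)) stop("image too small for requested pyramid level")
    out <- .binomial5(out)
    out <- out[seq(1, nrow(out), by = 2), seq(1, ncol(out), by = 2), drop = FALSE]
  }
  out
}

# separable [1,4,6,4,1]/16 filter with reflected borders
.binomial5 <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  conv1 <- function(x) {     # along rows of a matrix (filter columns)
    n <- nrow(x)
    idx <- function(i) pmin(pmax(i, 1L), n)  # replicate border
    k[1] * x[idx(seq_len(n) - 2L), , drop = FALSE] +
      k[2] * x[idx(seq_len(n) - 1L), , drop = FALSE] +
      k[3] * x +
      k[4] * x[idx(seq_len(n) + 1L), , drop = FALSE] +
      k[5] * x[idx(seq_len(n) + 2L), , drop = FALSE]
  }
  t(conv1(t(conv1(m))))
}

#' FFT-based normalized cross-correlation
#'
#' Computes the normalized cross-correlation coefficient of a template
#' against every fully-contained placement in an image. The correlation
#' numerator is evaluated in the frequency domain; the local image sums
#' needed for normalization use running (integral-image) sums, the standard
#' fast-NCC construction. Placements over (near-)constant image regions are
#' assigned coefficient 0.
#'
#' @param template Numeric matrix, strictly smaller than `image`, with
#'   nonzero variance.
#' @param image Numeric matrix.
#' @return Matrix of size `(nrow(image)-nrow(template)+1) x
#'   (ncol(image)-ncol(template)+1)`; entry `[u, v]` is the NCC of the
#'   template placed with top-left at 0-based `(u-1, v-1)`. Values lie in
#'   `[-1, 1]` up to roundoff.
#' @export
ncc_fft <- function(template, image) {
  stopifnot(is.matrix(template), is.matrix(image))
  h <- nrow(template); w <- ncol(template)
  H <- nrow(image); W <- ncol(image)
  if (h > H || w > W) stop("template larger than image")
  t0 <- template - mean(template)
  tss <- sum(t0^2)
  if (tss <= 0) stop("template has zero variance")
  P1 <- 2^ceiling(log2(H + h - 1)); P2 <- 2^ceiling(log2(W + w - 1))
  Ipad <- matrix(0, P1, P2); Ipad[1:H, 1:W] <- image
  Tpad <- matrix(0, P1, P2); Tpad[1:h, 1:w] <- t0
  num <- Re(fft(fft(Ipad) * Conj(fft(Tpad)), inverse = TRUE)) / (P1 * P2)
  num <- num[1:(H - h + 1), 1:(W - w + 1), drop = FALSE]
  # local sums over h x w windows via integral images (exact)
  S1 <- .win_sum(image, h, w)
  S2 <- .win_sum(image^2, h, w)
  nwin <- h * w
  varloc <- S2 - S1^2 / nwin
  varloc[varloc < 0] <- 0
  den <- sqrt(varloc * tss)
  cc <- num / den
  cc[den <= sqrt(tss) * 1e-10] <- 0
  pmin(pmax(cc, -1), 1)
}

# sliding-window sums by double cumulative sum
.win_sum <- function(m, h, w) {
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)   # transposed integral image
  cs <- t(cs)
  Z <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  Z[-1, -1] <- cs
  H <- nrow(m); W <- ncol(m)
  u <- 1:(H - h + 1); v <- 1:(W - w + 1)
  Z[u + h, v + w, drop = FALSE] - Z[u, v + w, drop = FALSE] -
    Z[u + h, v, drop = FALSE] + Z[u, v, drop = FALSE]
}

#' ROI specification for the thermal tracker
#'
#' The master ROI (mROI) is a rectangle, selected on the initialization
#' frame, whose content is the tracked template; slave ROIs (sROIs) are
#' ellipses that translate rigidly with the mROI. Coordinates are 0-based
#' `(row, col)` at full resolution.
#'
#' @param mroi_center `(row, col)` of the mROI center.
#' @param mroi_height,mroi_width Rectangle size in pixels.
#' @param srois List of sROIs, each `list(offset = c(drow, dcol),
#'   semi_axes = c(a, b))`, offsets relative to the mROI center.
#' @param gamma_th Correlation acceptance threshold in `(0, 1]`
#'   (default 0.995; frames with maximum correlation at or below it are
#'   discarded).
#' @param pyramid_level Gaussian pyramid level used for matching
#'   (default 1).
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(mroi_center, mroi_height, mroi_width, srois = list(),
                     gamma_th = 0.995, pyramid_level = 1L) {
  stopifnot(length(mroi_center) == 2, mroi_height > 0, mroi_width > 0,
            gamma_th > 0, gamma_th <= 1, pyramid_level >= 0)
  structure(list(mroi_center = as.numeric(mroi_center),
                 mroi_height = mroi_height, mroi_width = mroi_width,
                 srois = srois, gamma_th = gamma_th,
                 pyramid_level = as.integer(pyramid_level)),
            class = "roi_spec")
}

#' Track the master ROI across a thermal video
#'
#' For every frame: decimate through the Gaussian pyramid, segment skin
#' from background by Otsu's method, and locate the frame-0 template by
#' FFT-domain normalized cross-correlation, searching only placements whose
#' center falls on skin. The per-frame maximum correlation gamma is the
#' goodness index: frames with `gamma <= gamma_th` are discarded (NaN
#' centers) and tracking resumes when gamma exceeds the threshold again.
#' The template is the frame-0 crop and is never updated.
#'
#' @param video A [thermal_video()].
#' @param roi A [roi_spec()]; the mROI must lie inside the frame.
#' @return Object of class `track_result`: `mroi_centers` (`n x 2`, 0-based
#'   full-resolution pixels, NaN where discarded), `gamma`, `sroi_centers`
#'   (list per sROI), `n_discarded`, plus the ROI settings used.
#' @export
track_mroi <- function(video, roi) {
  stopifnot(inherits(video, "thermal_video"), inherits(roi, "roi_spec"))
  d <- dim(video$frames); R <- d[1]; C <- d[2]; n <- d[3]
  m <- 2^roi$pyramid_level
  cr <- roi$mroi_center[1]; cc <- roi$mroi_center[2]
  if (cr - roi$mroi_height / 2 < 0 || cr + roi$mroi_height / 2 > R - 1 ||
      cc - roi$mroi_width / 2 < 0 || cc + roi$mroi_width / 2 > C - 1)
    stop("mROI outside frame")

  # template: crop of the decimated frame 0, so a static video self-matches
  dec0 <- gaussian_pyramid(video$frames[, , 1], roi$pyramid_level)
  hd <- max(3L, round(roi$mroi_height / m))
  wd <- max(3L, round(roi$mroi_width / m))
  r0d <- round(cr / m - (hd - 1) / 2)            # 0-based top-left, decimated
  c0d <- round(cc / m - (wd - 1) / 2)
  r0d <- min(max(r0d, 0L), nrow(dec0) - hd)
  c0d <- min(max(c0d, 0L), ncol(dec0) - wd)
  template <- dec0[(r0d + 1):(r0d + hd), (c0d + 1):(c0d + wd), drop = FALSE]

  centers <- matrix(NaN, n, 2)
  gam <- rep(NA_real_, n)
  for (f in seq_len(n)) {
    dec <- gaussian_pyramid(video$frames[, , f], roi$pyramid_level)
    seg <- try(otsu_segment(dec), silent = TRUE)
    if (inherits(seg, "try-error")) next            # unsegmentable frame
    cc_surf <- ncc_fft(template, dec)
    # exclude placements whose center is off-skin
    uc <- round(seq_len(nrow(cc_surf)) - 1 + (hd - 1) / 2) + 1L
    vc <- round(seq_len(ncol(cc_surf)) - 1 + (wd - 1) / 2) + 1L
    on_skin <- seg$skin_mask[uc, vc, drop = FALSE]
    if (!any(on_skin)) next                          # empty search space
    cc_surf[!on_skin] <- -Inf
    best <- which.max(cc_surf)
    g <- cc_surf[best]
    gam[f] <- g
    if (g > roi$gamma_th) {
      ij <- arrayInd(best, dim(cc_surf))
      centers[f, ] <- m * c(ij[1] - 1 + (hd - 1) / 2,
                            ij[2] - 1 + (wd - 1) / 2)
    }
  }
  sroi_centers <- lapply(roi$srois, function(s) {
    sweep(centers - matrix(roi$mroi_center, n, 2, byrow = TRUE), 2,
          roi$mroi_center + s$offset, "+")
  })
  structure(list(mroi_centers = centers, gamma = gam,
                 sroi_centers = sroi_centers,
                 n_discarded = sum(!is.finite(centers[, 1])),
                 roi = roi, fs = video$fs),
            class = "track_result")
}

#' @export
print.track_result <- function(x, ...) {
  n <- nrow(x$mroi_centers)
  cat(sprintf("Track result: %d frames, %d discarded (gamma_th = %g)\n",
              n, x$n_discarded, x$roi$gamma_th))
  g <- x$gamma[is.finite(x$gamma)]
  if (length(g))
    cat(sprintf("  gamma: min %.4f, median %.4f, max %.4f\n",
                min(g), stats::median(g), max(g)))
  invisible(x)
}

#' Resultant motion trace
#'
#' Per-sample displacement container: non-negative resultant displacement
#' in pixels, its sampling rate, and a flag marking samples filled by
#' interpolation over discarded frames.
#'
#' @param values Numeric vector of displacements (pixels).
#' @param fs Sampling rate in Hz.
#' @param interpolated Logical vector (default all `FALSE`).
#' @return Object of class `motion_trace`.
#' @export
motion_trace <- function(values, fs, interpolated = NULL) {
  stopifnot(is.numeric(values), fs > 0, all(is.finite(values)),
            all(values >= 0))
  if (is.null(interpolated)) interpolated <- rep(FALSE, length(values))
  stopifnot(length(interpolated) == length(values))
  structure(list(values = as.numeric(values), fs = fs,
                 interpolated = as.logical(interpolated)),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("Motion trace: %d samples @ %g Hz, max %.2f px, %d interpolated\n",
              length(x$values), x$fs, max(x$values), sum(x$interpolated)))
  invisible(x)
}

#' @export
plot.motion_trace <- function(x, ...) {
  t <- (seq_along(x$values) - 1) / x$fs
  graphics::plot(t, x$values, type = "l", xlab = "time (s)",
                 ylab = "displacement (px)", ...)
  if (any(x$interpolated))
    graphics::points(t[x$interpolated], x$values[x$interpolated],
                     col = "red", pch = 20, cex = 0.5)
  invisible(x)
}

#' Reduce a tracking result to the resultant motion
#'
#' Combines the row and column displacement of the tracked center, relative
#' to the first retained frame, into the Euclidean resultant. Gaps from
#' discarded frames are filled by linear interpolation (flagged in
#' `interpolated`), and the trace is resampled to `target_fs` when it
#' differs from the video frame rate.
#'
#' @param track A [track_result()] with at least 2 retained frames.
#' @param target_fs Optional output rate in Hz (default: video rate).
#' @return A [motion_trace()].
#' @export
resultant_motion <- function(track, target_fs = NULL) {
  stopifnot(inherits(track, "track_result"))
  ctr <- track$mroi_centers
  ok <- is.finite(ctr[, 1]) & is.finite(ctr[, 2])
  if (sum(ok) < 2) stop("fewer than 2 retained frames")
  ref <- ctr[which(ok)[1], ]
  disp <- sqrt((ctr[, 1] - ref[1])^2 + (ctr[, 2] - ref[2])^2)
  n <- length(disp)
  filled <- stats::approx(which(ok), disp[ok], xout = seq_len(n),
                          rule = 2)$y
  interp <- !ok
  fs <- track$fs
  if (!is.null(target_fs) && abs(target_fs - fs) > 1e-9) {
    n_out <- round(n * target_fs / fs)
    t_in <- (seq_len(n) - 1) / fs
    t_out <- (seq_len(n_out) - 1) / target_fs
    filled2 <- stats::approx(t_in, filled, xout = t_out, rule = 2)$y
    interp2 <- stats::approx(t_in, as.numeric(interp), xout = t_out,
                             rule = 2)$y > 0
    return(motion_trace(pmax(filled2, 0), target_fs, interp2))
  }
  motion_trace(pmax(filled, 0), fs, interp)
}
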