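# shared fixture builders (everything generated in code, no stored data)

# bounded random walk in even-pixel steps, so level-1 decimated matching is
# exact and the 0.995 correlation gate retains all unoccluded frames
even_walk <- function(n, limit = 20, seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  s <- cumsum(2 * sample(-1:1, n - 1, replace = TRUE))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  pmax(pmin(c(0, s), limit), -limit)
}

make_tracking_video <- function(n_frames = 60, frame_size = c(120, 160),
                                occ = integer(0), seed = 2,
                                limit = 10) {
  traj <- cbind(even_walk(n_frames, limit, seed + 100),
                even_walk(n_frames, limit, seed + 200))
  synth_thermal_video(n_frames, frame_size, traj,
                      occlusion_frames = occ, seed = seed)
}

detector_roi <- function(sv, height = 30, width = 40, ...) {
  roi_spec(sv$truth$optode_centers[[1]][1, ], height, width, ...)
}

# brute-force spatial NCC oracle (independent of the FFT path)
ncc_spatial <- function(template, image) {
  h <- nrow(template); w <- ncol(template)
  t0 <- template - mean(template)
  tss <- sum(t0^2)
  out <- matrix(NA_real_, nrow(image) - h + 1, ncol(image) - w + 1)
  for (u in seq_len(nrow(out))) for (v in seq_len(ncol(out))) {
    win <- image[u:(u + h - 1), v:(v + w - 1)]
    d <- sqrt(sum((win - mean(win))^2) * tss)
    out[u, v] <- if (d <= sqrt(tss) * 1e-10) 0 else sum(t0 * (win - mean(win))) / d
  }
  pmin(pmax(out, -1), 1)
}

# exhaustive Otsu oracle: scan all 256 split points for max between-class
# variance over the same histogram
otsu_exhaustive <- function(frame, n_bins = 256L) {
  breaks <- seq(min(frame), max(frame), length.out = n_bins + 1L)
  bin <- findInterval(frame, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  best <- -Inf; kbest <- NA
  for (k in 1:(n_bins - 1)) {
    w0 <- sum(cnt[1:k]); w1 <- sum(cnt) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(cnt[1:k] * mids[1:k]) / w0
    m1 <- sum(cnt[(k + 1):n_bins] * mids[(k + 1):n_bins]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; kbest <- k }
  }
  breaks[kbest + 1]
}

# small, fast benchmark configuration for module-level tests
tiny_bench <- function(n_replicates = 1, seed = 11)
  benchmark_config(n_replicates = n_replicates, n_channels = 4,
                   duration = 150, seed = seed)
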