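#' Thermal video container
#'
#' A stack of per-pixel temperature frames (degrees Celsius) with a fixed
#' frame rate. Pixel coordinates are 0-based `(row, col)` throughout the
#' tracking code and all persisted outputs.
#'
#' @param frames Numeric array `rows x cols x n_frames`.
#' @param fs Frame rate in Hz.
#' @return Object of class `thermal_video`.
#' @export
thermal_video <- function(frames, fs) {
  stopifnot(is.array(frames), length(dim(frames)) == 3, fs > 0,
            all(is.finite(frames)))
  structure(list(frames = frames, fs = fs,
                 timestamps = (seq_len(dim(frames)[3]) - 1) / fs),
            class = "thermal_video")
}

#' @export
print.thermal_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Thermal video: %d frame(s) of %dx%d px @ %g Hz, %.2f-%.2f degC\n",
              d[3], d[1], d[2], x$fs, min(x$frames), max(x$frames)))
  invisible(x)
}

#' Synthetic thermal video of a translating face
#'
#' Renders a warm ellipse (the face) on a cooler background, with small
#' cooler discs at the optode positions (optodes sit between skin and
#' camera and read colder than skin), all rigidly translated frame by frame
#' along a given trajectory. The scene deliberately contains only what the
#' tracker models: translation, a segmentable skin/background temperature
#' contrast, and a distinctive template pattern (the optode discs). Frames
#' listed in `occlusion_frames` have the template region overwritten with
#' background temperature, emulating a spatial occlusion that must drop the
#' tracking correlation below threshold.
#'
#' @param n_frames Number of frames.
#' @param frame_size `c(rows, cols)` in pixels (default `c(240, 320)`).
#' @param trajectory `n_frames x 2` matrix of `(drow, dcol)` offsets in
#'   pixels relative to the base position (default all zero). The face
#'   ellipse must stay inside the frame at every offset.
#' @param fs Frame rate in Hz (default 10).
#' @param face_temp,bg_temp,optode_temp Temperatures in degrees Celsius
#'   (defaults 34, 23, 30).
#' @param face_center `(row, col)` of the ellipse center at offset zero,
#'   0-based; default frame center.
#' @param face_axes Ellipse semi-axes `(rows, cols)`; default scaled to the
#'   frame.
#' @param optode_offsets `k x 2` matrix of optode disc centers relative to
#'   the face center; default two detector discs on the forehead.
#' @param optode_radius Disc radius in pixels (default 7).
#' @param noise_sd Per-pixel i.i.d. noise SD in degrees C (default 0.03,
#'   the sensitivity class of research thermal cameras).
#' @param occlusion_frames Integer frame indices (1-based) to occlude.
#' @param occlusion_box `c(drow, dcol, height, width)`: box center relative
#'   to the face center plus size; default a box around the first optode.
#' @param seed Integer seed for the pixel noise.
#' @return List with `video` (a [thermal_video()]) and `truth`: the
#'   trajectory, per-frame 0-based optode centers (one `n x 2` matrix per
#'   optode), base geometry, and the occluded frame indices.
#' @export
synth_thermal_video <- function(n_frames, frame_size = c(240, 320),
                                trajectory = NULL, fs = 10,
                                face_temp = 34, bg_temp = 23,
                                optode_temp = 30,
                                face_center = NULL, face_axes = NULL,
                                optode_offsets = NULL, optode_radius = 7,
                                noise_sd = 0.03,
                                occlusion_frames = integer(0),
                                occlusion_box = NULL, seed = 1L) {
  stopifnot(n_frames >= 1, length(frame_size) == 2)
  R <- frame_size[1]; C <- frame_size[2]
  if (is.null(trajectory)) trajectory <- matrix(0, n_frames, 2)
  trajectory <- as.matrix(trajectory)
  stopifnot(nrow(trajectory) == n_frames, ncol(trajectory) == 2)
  if (is.null(face_center)) face_center <- c((R - 1) / 2, (C - 1) / 2)
  if (is.null(face_axes)) face_axes <- c(0.38 * R, 0.22 * C)
  a <- face_axes[1]; b <- face_axes[2]
  if (is.null(optode_offsets))
    optode_offsets <- rbind(c(-0.55 * a, -0.35 * b), c(-0.55 * a, 0.35 * b))
  optode_offsets <- as.matrix(optode_offsets)
  if (is.null(occlusion_box))
    occlusion_box <- c(optode_offsets[1, ], 8 * optode_radius, 8 * optode_radius)
  # face must stay inside the frame for every frame
  rmin <- face_center[1] + min(trajectory[, 1]) - a
  rmax <- face_center[1] + max(trajectory[, 1]) + a
  cmin <- face_center[2] + min(trajectory[, 2]) - b
  cmax <- face_center[2] + max(trajectory[, 2]) + b
  if (rmin < 0 || cmin < 0 || rmax > R - 1 || cmax > C - 1)
    stop("trajectory moves the face outside the frame")
  if (length(occlusion_frames) &&
      (min(occlusion_frames) < 1 || max(occlusion_frames) > n_frames))
    stop("occlusion_frames out of range")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows0 <- 0:(R - 1); cols0 <- 0:(C - 1)
  frames <- array(0, c(R, C, n_frames))
  k <- nrow(optode_offsets)
  centers <- lapply(seq_len(k), function(i)
    sweep(trajectory, 2, face_center + optode_offsets[i, ], "+"))
  for (f in seq_len(n_frames)) {
    cr <- face_center[1] + trajectory[f, 1]
    cc <- face_center[2] + trajectory[f, 2]
    ell <- outer(((rows0 - cr) / a)^2, ((cols0 - cc) / b)^2, "+") <= 1
    img <- matrix(bg_temp, R, C)
    img[ell] <- face_temp
    for (i in seq_len(k)) {
      oc <- centers[[i]][f, ]
      disc <- outer((rows0 - oc[1])^2, (cols0 - oc[2])^2, "+") <= optode_radius^2
      img[disc] <- optode_temp
    }
    if (f %in% occlusion_frames) {
      obr <- cr + occlusion_box[1]; obc <- cc + occlusion_box[2]
      r0 <- max(0, round(obr - occlusion_box[3] / 2))
      r1 <- min(R - 1, round(obr + occlusion_box[3] / 2))
      c0 <- max(0, round(obc - occlusion_box[4] / 2))
      c1 <- min(C - 1, round(obc + occlusion_box[4] / 2))
      img[(r0:r1) + 1, (c0:c1) + 1] <- bg_temp
    }
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(R * C, 0, noise_sd), R, C)
    frames[, , f] <- img
  }
  list(video = thermal_video(frames, fs),
       truth = list(trajectory = trajectory,
                    optode_centers = centers,
                    face_center = face_center, face_axes = face_axes,
                    optode_offsets = optode_offsets,
                    optode_radius = optode_radius,
                    occlusion_frames = sort(unique(occlusion_frames))))
}
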