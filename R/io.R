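#' Read a uniformly sampled time-series CSV
#'
#' Expects a header row and a first column of time in seconds; remaining
#' columns are channels. The time base must be strictly increasing and
#' uniform (maximum jitter below 10% of the median period); the sampling
#' rate is inferred from the median interval.
#'
#' @param path CSV file path.
#' @return An [fnirs_recording()] (channel labels from the header).
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("need a time column plus at least one channel")
  if (anyNA(df)) {
    bad <- which(!stats::complete.cases(df))[1]
    stop("missing/ragged values at data line ", bad, " of ", path)
  }
  tt <- df[[1]]
  if (any(diff(tt) <= 0)) {
    bad <- which(diff(tt) <= 0)[1] + 1L
    stop("non-monotone or duplicated time stamps at data line ", bad)
  }
  period <- stats::median(diff(tt))
  if (max(abs(diff(tt) - period)) > 0.1 * period)
    stop("non-uniform sampling (jitter above 10% of the period)")
  dat <- t(as.matrix(df[, -1, drop = FALSE]))
  fnirs_recording(dat, fs = 1 / period, channel_labels = colnames(df)[-1])
}

#' Write an fNIRS recording as CSV
#'
#' Header `time,<ch1>,...,<chN>`, time in seconds, full double precision.
#'
#' @param recording An [fnirs_recording()].
#' @param path Output path.
#' @export
write_timeseries_csv <- function(recording, path) {
  stopifnot(inherits(recording, "fnirs_recording"))
  n <- ncol(recording$data)
  df <- data.frame(time = (seq_len(n) - 1) / recording$fs,
                   t(recording$data), check.names = FALSE)
  names(df) <- c("time", recording$channel_labels)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a motion trace as CSV
#'
#' Columns `time,displacement_px,gamma,interpolated`; `gamma` comes from a
#' matching [track_mroi()] result when given, else `NA`.
#'
#' @param trace A [motion_trace()].
#' @param path Output path.
#' @param track Optional [track_mroi()] result supplying per-frame gamma.
#' @export
write_motion_csv <- function(trace, path, track = NULL) {
  stopifnot(inherits(trace, "motion_trace"))
  n <- length(trace$values)
  gamma <- rep(NA_real_, n)
  if (!is.null(track) && length(track$gamma) == n) gamma <- track$gamma
  df <- data.frame(time = (seq_len(n) - 1) / trace$fs,
                   displacement_px = trace$values, gamma = gamma,
                   interpolated = as.integer(trace$interpolated))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a motion trace CSV
#'
#' @param path CSV written by [write_motion_csv()].
#' @return A [motion_trace()].
#' @export
read_motion_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time", "displacement_px") %in% names(df)))
  period <- stats::median(diff(df$time))
  interp <- if ("interpolated" %in% names(df)) df$interpolated > 0 else NULL
  motion_trace(df$displacement_px, 1 / period, interp)
}

#' Write a thermal video as a multipage TIFF
#'
#' One 32-bit page per frame. The TIFF library stores floats clipped to
#' `[0, 1]`, so temperatures are written affinely normalized; the
#' calibration (temperature range and frame rate) goes to a JSON sidecar
#' `<path>.json`, which [read_thermal_tiff()] uses to restore degrees C.
#'
#' @param video A [thermal_video()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_thermal_tiff <- function(video, path) {
  stopifnot(inherits(video, "thermal_video"))
  lo <- min(video$frames); hi <- max(video$frames)
  span <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(video$frames)[3]), function(f)
    (video$frames[, , f] - lo) / span)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(temp_min = lo, temp_max = lo + span,
                            fs = video$fs,
                            n_frames = dim(video$frames)[3]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multipage thermal TIFF
#'
#' @param path TIFF path; the `<path>.json` sidecar written by
#'   [write_thermal_tiff()] supplies the temperature calibration and frame
#'   rate (`fs` and `temp_range` override it).
#' @param fs Frame rate in Hz (required if there is no sidecar).
#' @param temp_range Optional `c(min, max)` degrees C.
#' @return A [thermal_video()].
#' @export
read_thermal_tiff <- function(path, fs = NULL, temp_range = NULL) {
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(fs)) fs <- meta$fs
    if (is.null(temp_range)) temp_range <- c(meta$temp_min, meta$temp_max)
  }
  if (is.null(fs)) stop("frame rate unknown: no sidecar and no fs given")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!length(pages)) stop("empty TIFF")
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  if (length(d) != 2) stop("expected single-channel pages")
  for (p in pages) if (!identical(dim(p), d)) stop("mixed page dimensions")
  frames <- array(unlist(pages), c(d[1], d[2], length(pages)))
  if (!is.null(temp_range))
    frames <- temp_range[1] + frames * (temp_range[2] - temp_range[1])
  thermal_video(frames, fs)
}

#' Write an ROI specification as JSON
#'
#' @param roi A [roi_spec()].
#' @param path Output path.
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "roi_spec"))
  jsonlite::write_json(
    list(mroi = list(center = roi$mroi_center, height = roi$mroi_height,
                     width = roi$mroi_width),
         srois = lapply(roi$srois, function(s)
           list(offset = s$offset, semi_axes = s$semi_axes)),
         gamma_th = roi$gamma_th, pyramid_level = roi$pyramid_level),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI specification from JSON
#'
#' @param path JSON path as written by [write_roi_json()].
#' @return A [roi_spec()].
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  srois <- list()
  if (!is.null(j$srois) && length(j$srois))
    srois <- lapply(seq_len(NROW(j$srois)), function(i)
      if (is.data.frame(j$srois)) list(offset = unlist(j$srois$offset[i]),
                                       semi_axes = unlist(j$srois$semi_axes[i]))
      else j$srois[[i]])
  roi_spec(j$mroi$center, j$mroi$height, j$mroi$width, srois,
           gamma_th = j$gamma_th %||% 0.995,
           pyramid_level = j$pyramid_level %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a provenance record
#'
#' Machine-readable record of how an output was produced: the settings
#' used, seeds, and package/R versions.
#'
#' @param path Output JSON path.
#' @param settings Named list of run settings.
#' @export
write_provenance <- function(path, settings = list()) {
  jsonlite::write_json(
    list(package = "nirsmotion",
         version = as.character(utils::packageVersion("nirsmotion")),
         r_version = R.version.string,
         settings = settings),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
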