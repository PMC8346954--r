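#' Set of discrete motion events
#'
#' Describes head-movement events abstractly as transient `spike` events
#' (the head moves and returns: yawns, frowns) or persistent `shift` events
#' (the optode settles at a new position: head tilt). Each event carries a
#' displacement magnitude in pixels (how far the optode moves in the thermal
#' frame) and an artifact gain in signal units per pixel (how strongly the
#' movement couples into the optical signal).
#'
#' @param times Event times in seconds.
#' @param kinds Character vector, `"spike"` or `"shift"` per event.
#' @param px_magnitudes Displacement magnitude per event, pixels.
#' @param artifact_gains Artifact coupling per event, signal units per pixel.
#' @return Object of class `motion_events`.
#' @export
motion_events <- function(times, kinds, px_magnitudes, artifact_gains) {
  stopifnot(length(times) == length(kinds),
            length(times) == length(px_magnitudes),
            length(times) == length(artifact_gains),
            all(kinds %in% c("spike", "shift")),
            all(is.finite(times)), all(is.finite(px_magnitudes)),
            all(is.finite(artifact_gains)))
  o <- order(times)
  structure(list(times = as.numeric(times)[o], kinds = as.character(kinds)[o],
                 px_magnitudes = as.numeric(px_magnitudes)[o],
                 artifact_gains = as.numeric(artifact_gains)[o]),
            class = "motion_events")
}

#' @export
print.motion_events <- function(x, ...) {
  cat(sprintf("Motion events: %d spike(s), %d shift(s)\n",
              sum(x$kinds == "spike"), sum(x$kinds == "shift")))
  invisible(x)
}

#' Synthesize a displacement trace from motion events
#'
#' Spike events contribute a Gaussian displacement pulse (the optode moves
#' away and comes back); shift events contribute a smooth sigmoidal step
#' (the optode moves and stays). Displacement is the non-negative resultant
#' in pixels, as delivered by the thermal tracker.
#'
#' @param events A [motion_events()] object; all event times must fall
#'   within `duration`.
#' @param fs Sampling rate in Hz.
#' @param duration Trace duration in seconds.
#' @param spike_width Gaussian SD of a spike pulse, seconds (default 0.5).
#' @param shift_rise Sigmoid time constant of a shift, seconds (default 0.3).
#' @return A [motion_trace()].
#' @export
synth_motion_trace <- function(events, fs, duration, spike_width = 0.5,
                               shift_rise = 0.3) {
  stopifnot(inherits(events, "motion_events"), fs > 0, duration > 0)
  if (length(events$times) && (min(events$times) < 0 ||
                               max(events$times) > duration))
    stop("event times outside recording duration")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  m <- numeric(n)
  for (i in seq_along(events$times)) {
    t0 <- events$times[i]; mag <- events$px_magnitudes[i]
    m <- m + if (events$kinds[i] == "spike")
      mag * exp(-(t - t0)^2 / (2 * spike_width^2))
    else
      mag / (1 + exp(-(t - t0) / shift_rise))
  }
  motion_trace(m, fs)
}

#' Inject motion-coupled artifacts into an fNIRS recording
#'
#' Additively corrupts each channel with one artifact per event. A `spike`
#' event adds a transient deflection shaped like a Gaussian pulse; a `shift`
#' event adds a persistent step from the event time onward. The artifact
#' amplitude of event *e* on channel *c* is
#' `artifact_gain[e] * channel_gains[c] * motion(t_e)` -- linear in the
#' displacement magnitude at the event time, with independent per-channel
#' gains so that a movement can corrupt some channels more than others.
#'
#' @param recording An [fnirs_recording()].
#' @param motion A [motion_trace()] sample-aligned with the recording
#'   (same length and rate).
#' @param events A [motion_events()] object.
#' @param channel_gains Numeric vector of per-channel coupling gains
#'   (default all 1). Sign is respected, so artifacts may deflect either way.
#' @param spike_width Gaussian SD of the spike artifact, seconds.
#' @return List with `recording` (corrupted), `clean` (the input),
#'   `artifact` (channels x time matrix actually added, so that
#'   `corrupted - clean == artifact` exactly).
#' @export
inject_motion_artifacts <- function(recording, motion, events,
                                    channel_gains = NULL, spike_width = 0.5) {
  stopifnot(inherits(recording, "fnirs_recording"),
            inherits(motion, "motion_trace"),
            inherits(events, "motion_events"))
  n <- ncol(recording$data)
  if (length(motion$values) != n || abs(motion$fs - recording$fs) > 1e-9)
    stop("motion trace not sample-aligned with recording")
  nc <- nrow(recording$data)
  if (is.null(channel_gains)) channel_gains <- rep(1, nc)
  stopifnot(length(channel_gains) == nc)
  t <- (seq_len(n) - 1) / recording$fs
  art1 <- numeric(n)                       # unit-gain artifact waveform
  for (i in seq_along(events$times)) {
    t0 <- events$times[i]
    m0 <- motion$values[which.min(abs(t - t0))]
    amp <- events$artifact_gains[i] * m0
    art1 <- art1 + if (events$kinds[i] == "spike")
      amp * exp(-(t - t0)^2 / (2 * spike_width^2))
    else
      amp * as.numeric(t >= t0)
  }
  artifact <- outer(channel_gains, art1)
  out <- recording
  out$data <- recording$data + artifact
  list(recording = out, clean = recording, artifact = artifact)
}
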