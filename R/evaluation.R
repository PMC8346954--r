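#' GLM fit of a channel against the activation regressor
#'
#' Ordinary least squares of the signal on `[regressor, intercept]`, the
#' canonical single-regressor GLM used to assess block activation. Reports
#' the regression weight beta, its standard error, the t statistic
#' `beta / SE(beta)`, the residual SD, and `sigma_rest`, the SD of the
#' signal over resting samples (used by [snr_metric()]).
#'
#' @param signal Numeric vector.
#' @param regressor Numeric vector, same length, nonconstant (the
#'   HRF-convolved boxcar).
#' @param rest_mask Optional logical vector marking rest samples
#'   (boxcar == 0); without it `sigma_rest` is `NA`.
#' @return Object of class `hrf_glm`.
#' @export
glm_hrf <- function(signal, regressor, rest_mask = NULL) {
  stopifnot(length(signal) == length(regressor), all(is.finite(signal)),
            all(is.finite(regressor)))
  if (stats::sd(regressor) == 0) stop("constant regressor")
  X <- cbind(regressor = regressor, intercept = 1)
  fit <- stats::lm.fit(X, signal)
  res <- fit$residuals
  df <- length(signal) - 2L
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * XtXinv[1, 1])
  beta <- unname(fit$coefficients[1])
  sigma_rest <- if (is.null(rest_mask)) NA_real_ else {
    stopifnot(length(rest_mask) == length(signal))
    stats::sd(signal[rest_mask])
  }
  structure(list(beta = beta, beta_se = se,
                 t_stat = if (se > 0) beta / se else sign(beta) * Inf,
                 residual_sd = sqrt(mean(res^2) * length(res) / df),
                 sigma_rest = sigma_rest),
            class = "hrf_glm")
}

#' @export
print.hrf_glm <- function(x, ...) {
  cat(sprintf("HRF GLM: beta = %.4g (SE %.3g), t = %.3f, sigma_rest = %.4g\n",
              x$beta, x$beta_se, x$t_stat, x$sigma_rest))
  invisible(x)
}

#' Signal-to-noise ratio of an activation fit
#'
#' `SNR = beta / sigma_rest`: the fitted activation amplitude divided by
#' the signal's standard deviation over the resting periods. Invariant to
#' rescaling the whole signal.
#'
#' @param glm An [glm_hrf()] result with `sigma_rest > 0`.
#' @return Unitless SNR.
#' @export
snr_metric <- function(glm) {
  stopifnot(inherits(glm, "hrf_glm"))
  if (!is.finite(glm$sigma_rest) || glm$sigma_rest <= 0)
    stop("sigma_rest must be positive (fit with a rest_mask)")
  glm$beta / glm$sigma_rest
}

#' Mean squared error against the known clean signal
#'
#' @param corrected,clean Equal-length numeric vectors.
#' @return Mean of squared differences (signal units squared).
#' @export
mse_metric <- function(corrected, clean) {
  stopifnot(length(corrected) == length(clean))
  mean((corrected - clean)^2)
}

#' Paired t test
#'
#' Two-sided paired Student t test, `t = mean(d) / (sd(d)/sqrt(n))` with
#' `d = a - b` and `df = n - 1`. Used across channel-averaged metric values
#' to compare correction methods.
#'
#' @param a,b Equal-length numeric vectors, `n >= 2`; the differences must
#'   have nonzero variance.
#' @return List with `t`, `df`, `p`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero-variance differences")
  n <- length(d)
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1L))
}

#' Simulation benchmark configuration
#'
#' Defines the study conditions of the validation harness: independent
#' seeded replicates stand in for subjects (default 16), each an 8-channel,
#' 5-minute, 10 Hz recording with a 20 s on / 20 s off block paradigm,
#' randomly timed motion events (8 transient spikes, 2 persistent shifts)
#' and motion-coupled artifacts with per-channel gains.
#'
#' @param n_replicates Number of simulated subjects (default 16).
#' @param n_channels Channels per recording (default 8, over 2 detectors).
#' @param fs Sampling rate, Hz (default 10).
#' @param duration Recording length, seconds (default 300).
#' @param block_duration,block_gap Task/rest block lengths, seconds
#'   (default 20/20).
#' @param activation_amplitude Injected activation peak, signal units
#'   (default 0.5; the injected-to-physiological amplitude ratio is an
#'   exposed parameter, not a fixed constant).
#' @param n_spikes,n_shifts Motion events per replicate (defaults 8, 2).
#' @param spike_gain,shift_gain Ranges of per-event artifact gains, signal
#'   units per pixel of displacement.
#' @param seed Base seed; replicate r uses `seed + 7919 * r`.
#' @return Object of class `benchmark_config`.
#' @export
benchmark_config <- function(n_replicates = 16, n_channels = 8, fs = 10,
                             duration = 300, block_duration = 20,
                             block_gap = 20, activation_amplitude = 0.5,
                             n_spikes = 8, n_shifts = 2,
                             spike_gain = c(0.15, 0.45),
                             shift_gain = c(0.10, 0.30), seed = 1L) {
  stopifnot(n_replicates >= 1, n_channels >= 2, fs > 0, duration >= 60)
  structure(list(n_replicates = n_replicates, n_channels = n_channels,
                 fs = fs, duration = duration,
                 block_duration = block_duration, block_gap = block_gap,
                 activation_amplitude = activation_amplitude,
                 n_spikes = n_spikes, n_shifts = n_shifts,
                 spike_gain = spike_gain, shift_gain = shift_gain,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Simulate one benchmark subject
#'
#' Builds the full ground-truthed scenario for one replicate: resting-state
#' O2Hb channels, a motion trace from randomly timed spike/shift events,
#' motion-coupled artifacts with per-channel gains (random sign per event),
#' the injected block activation, and an anticorrelated HHb counterpart
#' sharing the same artifacts (used by the CBSI baseline).
#'
#' @param config A [benchmark_config()].
#' @param replicate Replicate index (the "subject").
#' @return List: `corrupted`, `clean` ([fnirs_recording()]s; clean = resting
#'   + activation), `hhb_corrupted`, `regressor`, `rest_mask`, `trace`
#'   ([motion_trace()]), `traces` (per-detector list), `events`, `paradigm`.
#' @export
simulate_subject <- function(config, replicate = 1) {
  stopifnot(inherits(config, "benchmark_config"))
  seed <- config$seed + 7919L * as.integer(replicate)
  fs <- config$fs; dur <- config$duration
  period <- config$block_duration + config$block_gap
  onsets <- seq(config$block_gap, dur - config$block_duration, by = period)
  par <- paradigm(onsets, config$block_duration, dur)

  rest <- synth_resting_fnirs(fs, dur, config$n_channels, seed = seed)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  ns <- config$n_spikes; nh <- config$n_shifts
  times <- c(sort(stats::runif(ns, 15, dur - 20)),
             sort(stats::runif(nh, 60, dur - 60)))
  kinds <- c(rep("spike", ns), rep("shift", nh))
  px <- stats::runif(ns + nh, 2, 8)
  gains <- c(stats::runif(ns, config$spike_gain[1], config$spike_gain[2]),
             stats::runif(nh, config$shift_gain[1], config$shift_gain[2])) *
    sample(c(-1, 1), ns + nh, replace = TRUE)
  ev <- motion_events(times, kinds, px, gains)
  trace <- synth_motion_trace(ev, fs, dur)
  ch_gains <- stats::runif(config$n_channels, 0.4, 1.6)

  inj <- inject_motion_artifacts(rest, trace, ev, ch_gains)
  act_cor <- add_activation(inj$recording, par,
                            amplitude = config$activation_amplitude)
  act_cln <- add_activation(rest, par,
                            amplitude = config$activation_amplitude)

  # anticorrelated HHb partner: ~1/3 amplitude, own phases, same artifacts
  rest_h <- synth_resting_fnirs(fs, dur, config$n_channels, seed = seed + 2L)
  hhb <- rest_h
  hhb$data <- rest_h$data / 3 + inj$artifact -
    matrix((config$activation_amplitude / 3) * act_cor$regressor,
           config$n_channels, ncol(rest_h$data), byrow = TRUE)
  hhb$chromophore <- rep("HHb", config$n_channels)

  dets <- unique(rest$detector)
  traces <- stats::setNames(rep(list(trace), length(dets)), dets)
  list(corrupted = act_cor$recording, clean = act_cln$recording,
       hhb_corrupted = hhb, regressor = act_cor$regressor,
       rest_mask = act_cor$rest_mask, trace = trace, traces = traces,
       events = ev, paradigm = par)
}

# score one channels-x-time matrix: per-channel beta, t, SNR, MSE
.score_channels <- function(data, clean, regressor, rest_mask) {
  t(vapply(seq_len(nrow(data)), function(ch) {
    g <- glm_hrf(data[ch, ], regressor, rest_mask)
    c(beta = g$beta, t_stat = g$t_stat, snr = snr_metric(g),
      mse = mse_metric(data[ch, ], clean[ch, ]))
  }, numeric(4)))
}

# apply one correction method to a simulated subject
.apply_method <- function(method, sub, config, wparams, thr = NULL) {
  cc <- correction_config(threshold = if (is.null(thr)) 0.6 else thr)
  rec <- sub$corrupted
  switch(method,
    none = rec$data,
    proposed = correct_recording(rec, sub$traces, cc, wparams)$corrected$data,
    wavelet = t(apply(rec$data, 1, wavelet_iqr_correct)),
    pca = pca_correct(rec, 1L)$recording$data,
    spline = {
      segs <- motion_segments(sub$trace)
      t(apply(rec$data, 1, spline_mara_correct, segments = segs))
    },
    cbsi = {
      out <- rec$data
      for (ch in seq_len(nrow(out)))
        out[ch, ] <- cbsi_correct(rec$data[ch, ], sub$hhb_corrupted$data[ch, ])$hbo
      out
    },
    stop("unknown method: ", method))
}

#' Run the simulation benchmark for one method
#'
#' Simulates every replicate, applies the requested correction, and scores
#' each channel by GLM beta, t statistic, SNR and MSE against the clean
#' ground truth.
#'
#' @param config A [benchmark_config()].
#' @param method One of `"none"`, `"proposed"`, `"wavelet"`, `"pca"`,
#'   `"spline"`, `"cbsi"`.
#' @param threshold Proposed-method threshold (default 0.6).
#' @param wparams A [wavelet_params()].
#' @return Data frame: replicate, channel, method, threshold, beta, t_stat,
#'   snr, mse.
#' @export
run_benchmark <- function(config, method = "proposed", threshold = 0.6,
                          wparams = wavelet_params()) {
  do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
    sub <- simulate_subject(config, r)
    dat <- .apply_method(method, sub, config, wparams, threshold)
    sc <- .score_channels(dat, sub$clean$data, sub$regressor, sub$rest_mask)
    data.frame(replicate = r, channel = seq_len(nrow(sc)), method = method,
               threshold = if (method == "proposed") threshold else NA_real_,
               beta = sc[, "beta"], t_stat = sc[, "t_stat"],
               snr = sc[, "snr"], mse = sc[, "mse"], row.names = NULL)
  }))
}

#' Threshold sweep of the proposed correction
#'
#' Runs the full simulate-corrupt-correct-GLM chain at each candidate
#' threshold, reusing the wavelet transforms across thresholds (the
#' scalogram and coherence do not depend on the threshold, only the mask
#' does). Deterministic given the config seed.
#'
#' @param config A [benchmark_config()].
#' @param thresholds Candidate thresholds (default `c(0.4, ..., 0.8)`).
#' @param combine_rule Mask combination rule.
#' @param wparams A [wavelet_params()].
#' @return List: `metrics` (long data frame, one row per replicate x
#'   channel x threshold, plus `"none"` rows for the uncorrected data) and
#'   `summary` (mean and SD of SNR and MSE per threshold).
#' @export
threshold_sweep <- function(config, thresholds = c(0.4, 0.5, 0.6, 0.7, 0.8),
                            combine_rule = "intersection",
                            wparams = wavelet_params()) {
  rows <- list()
  for (r in seq_len(config$n_replicates)) {
    sub <- simulate_subject(config, r)
    rec <- sub$corrupted
    msc <- cwt_morse(sub$trace$values, rec$fs, wparams)
    sc0 <- .score_channels(rec$data, sub$clean$data, sub$regressor,
                           sub$rest_mask)
    rows[[length(rows) + 1]] <- data.frame(
      replicate = r, channel = seq_len(nrow(sc0)), method = "none",
      threshold = NA_real_, beta = sc0[, "beta"], t_stat = sc0[, "t_stat"],
      snr = sc0[, "snr"], mse = sc0[, "mse"], row.names = NULL)
    for (ch in seq_len(nrow(rec$data))) {
      sig <- rec$data[ch, ]
      sig_sc <- cwt_morse(sig, rec$fs, wparams)
      coh <- wcoh_morlet(sig, sub$trace$values, rec$fs, wparams)
      for (thr in thresholds) {
        cfg <- correction_config(thr, combine_rule)
        mask <- build_mask(msc, coh, cfg)
        cor <- icwt(sig_sc, mask)
        g <- glm_hrf(cor, sub$regressor, sub$rest_mask)
        rows[[length(rows) + 1]] <- data.frame(
          replicate = r, channel = ch, method = "proposed", threshold = thr,
          beta = g$beta, t_stat = g$t_stat, snr = snr_metric(g),
          mse = mse_metric(cor, sub$clean$data[ch, ]), row.names = NULL)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  prop <- metrics[metrics$method == "proposed", ]
  summ <- do.call(rbind, lapply(split(prop, prop$threshold), function(d)
    data.frame(threshold = d$threshold[1],
               snr_mean = mean(d$snr), snr_sd = stats::sd(d$snr),
               mse_mean = mean(d$mse), mse_sd = stats::sd(d$mse),
               row.names = NULL)))
  list(metrics = metrics, summary = summ[order(summ$threshold), ])
}

#' Compare correction methods on the benchmark
#'
#' Scores every method on the same simulated replicates, averages each
#' metric over replicates within channel, and runs a paired t test across
#' channels (df = n_channels - 1) for the proposed method against each
#' other method -- the statistical design of a per-channel,
#' subject-averaged method comparison. A self-comparison has zero-variance
#' differences and is reported as non-applicable (`NA`).
#'
#' @param config A [benchmark_config()].
#' @param methods Methods to score (default all six).
#' @param threshold Proposed-method threshold.
#' @param wparams A [wavelet_params()].
#' @return List: `metrics` (long data frame), `channel_means` (per channel
#'   x method), `ttests` (proposed vs. each method, per metric).
#' @export
compare_methods <- function(config,
                            methods = c("none", "proposed", "wavelet", "pca",
                                        "spline", "cbsi"),
                            threshold = 0.6, wparams = wavelet_params()) {
  stopifnot(length(methods) >= 2)
  metrics <- do.call(rbind, lapply(methods, function(m)
    run_benchmark(config, m, threshold, wparams)))
  key <- interaction(metrics$channel, metrics$method, drop = TRUE)
  channel_means <- do.call(rbind, lapply(split(metrics, key), function(d)
    data.frame(channel = d$channel[1], method = d$method[1],
               beta = mean(d$beta), t_stat = mean(d$t_stat),
               snr = mean(d$snr), mse = mean(d$mse), row.names = NULL)))
  ref <- if ("proposed" %in% methods) "proposed" else methods[1]
  refm <- channel_means[channel_means$method == ref, ]
  refm <- refm[order(refm$channel), ]
  tt <- list()
  for (m in methods) {       # includes ref vs ref: reported non-applicable
    om <- channel_means[channel_means$method == m, ]
    om <- om[order(om$channel), ]
    for (met in c("snr", "mse", "beta", "t_stat")) {
      res <- tryCatch(paired_ttest(refm[[met]], om[[met]]),
                      error = function(e) list(t = NA_real_,
                                               df = nrow(refm) - 1L,
                                               p = NA_real_))
      tt[[length(tt) + 1]] <- data.frame(
        comparison = paste(ref, "vs", m), metric = met,
        t = res$t, df = res$df, p = res$p, row.names = NULL)
    }
  }
  list(metrics = metrics, channel_means = channel_means,
       ttests = do.call(rbind, tt))
}
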