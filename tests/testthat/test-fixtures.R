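test_that("boxcar places amplitude exactly inside half-open blocks", {
  p <- paradigm(10, 10, 30)
  b <- make_boxcar(p, 10)
  expect_length(b, 300)
  expect_equal(b, c(rep(0, 100), rep(1, 100), rep(0, 100)))

  expect_equal(make_boxcar(paradigm(numeric(0), 10, 30), 10), rep(0, 300))

  # 8 blocks of 20 s every 40 s over 5 min: 1600 task samples by hand count
  p5 <- paradigm(seq(0, 280, by = 40), 20, 300)
  b5 <- make_boxcar(p5, 10)
  expect_equal(sum(b5 > 0), 8 * 200)
})

test_that("paradigm validation rejects bad block layouts", {
  expect_error(paradigm(c(10, 5), 2, 60), "increasing")
  expect_error(paradigm(c(10, 11), 5, 60), "overlap")
  expect_error(paradigm(55, 10, 60), "past total_duration")
  expect_silent(paradigm(c(0, 20), 20, 60))   # back-to-back blocks are legal
})

test_that("canonical HRF has unit peak near 6 s, an undershoot, and decays", {
  fs <- 10
  h <- canonical_hrf(fs)
  expect_equal(max(h), 1.0)
  tpeak <- (which.max(h) - 1) / fs
  expect_lte(abs(tpeak - 6), 1)
  expect_lt(min(h), 0)                      # undershoot present
  expect_gt(min(h), -0.25)                  # ... and smaller than the peak
  expect_lt(max(abs(h[seq(31 * fs, length(h))])), 0.01)
  # numeric quadrature: net integral is positive
  expect_gt(sum(h) / fs, 0)
})

test_that("resting-state generator is seeded and spectrally faithful", {
  fs <- 10
  r1 <- synth_resting_fnirs(fs, 300, 2, seed = 7)
  r2 <- synth_resting_fnirs(fs, 300, 2, seed = 7)
  expect_identical(r1$data, r2$data)

  zero <- synth_resting_fnirs(fs, 60, 1,
                              amplitudes = c(cardiac = 0, respiratory = 0,
                                             mayer = 0, drift = 0, noise = 0))
  expect_true(all(zero$data == 0))

  expect_error(synth_resting_fnirs(2, 300), "cardiac")
  expect_error(synth_resting_fnirs(10, 30), "60 s")

  # periodogram oracle: a local spectral maximum within 0.05 Hz of each
  # configured band center
  x <- r1$data[1, ]
  n <- length(x)
  pgram <- Mod(fft(x - mean(x))[1:(n / 2)])^2
  sm <- stats::filter(pgram, rep(1 / 5, 5), sides = 2)
  freq <- (0:(n / 2 - 1)) * fs / n
  inner <- 4:(length(sm) - 3)
  is_max <- inner[which(sm[inner] > sm[inner - 1] & sm[inner] >= sm[inner + 1])]
  peaks <- freq[is_max]
  for (f0 in c(1.1, 0.25, 0.1))
    expect_lte(min(abs(peaks - f0)), 0.05, label = paste("peak near", f0))
})

test_that("artifact injection is additive with exact ground truth", {
  fs <- 10; dur <- 120; n <- fs * dur
  rec <- synth_resting_fnirs(fs, dur, 2, seed = 3)
  trace <- motion_trace(rep(1, n), fs)

  # zero gains: identity
  ev <- motion_events(60, "spike", 1, 1)
  out0 <- inject_motion_artifacts(rec, trace, ev, channel_gains = c(0, 0))
  expect_identical(out0$recording$data, rec$data)

  # one +0.5 shift at t = 60 on an otherwise-zero channel
  zero <- fnirs_recording(matrix(0, 1, n), fs)
  evs <- motion_events(60, "shift", 1, 0.5)
  out <- inject_motion_artifacts(zero, trace, evs)
  d <- out$recording$data[1, ]
  expect_equal(mean(d[(60 * fs + 1):n]) - mean(d[1:(60 * fs)]), 0.5)

  # spike peaks within 1 s of the event time (argmax oracle)
  evp <- motion_events(45, "spike", 1, 0.8)
  outp <- inject_motion_artifacts(zero, trace, evp)
  tpk <- (which.max(abs(outp$recording$data[1, ])) - 1) / fs
  expect_lte(abs(tpk - 45), 1)

  # conservation: corrupted - clean reconstructs the artifact exactly
  out2 <- inject_motion_artifacts(rec, trace, evs, channel_gains = c(1, 0.5))
  expect_equal(out2$recording$data - rec$data, out2$artifact,
               ignore_attr = TRUE)

  short <- motion_trace(rep(1, n - 1), fs)
  expect_error(inject_motion_artifacts(rec, short, evs), "aligned")
})

test_that("activation injection is causal and recovers beta exactly", {
  fs <- 10; dur <- 200
  rec <- synth_resting_fnirs(fs, dur, 3, seed = 9)
  p <- paradigm(c(30, 90, 150), 20, dur)

  id <- add_activation(rec, p, amplitude = 0)
  expect_equal(id$recording$data, rec$data)

  out <- add_activation(rec, p, amplitude = 0.7)
  diff <- out$recording$data - rec$data
  expect_true(all(diff[, 1:(30 * fs)] == 0))      # nothing before first onset

  # OLS oracle on the difference: beta equals the injected amplitude
  for (ch in 1:3) {
    fit <- stats::lm(diff[ch, ] ~ out$regressor)
    expect_equal(unname(stats::coef(fit)[2]), 0.7, tolerance = 1e-12)
  }
  expect_equal(max(out$regressor), 1.0)
  expect_equal(out$rest_mask, make_boxcar(p, fs) == 0)
})

test_that("thermal video generator matches its own geometry", {
  sv <- synth_thermal_video(3, c(80, 100), noise_sd = 0, seed = 1)
  expect_identical(sv$video$frames[, , 1], sv$video$frames[, , 3])

  # Otsu mask covers the ellipse and excludes the background, noise-free
  f1 <- sv$video$frames[, , 1]
  seg <- otsu_segment(f1)
  ell <- f1 > 23                      # generator: everything above background
  expect_true(all(seg$skin_mask == ell))

  # occlusion destroys the template pattern: best NCC drops below the gate
  svo <- synth_thermal_video(3, c(120, 160), occlusion_frames = 2, seed = 4)
  ctr <- round(svo$truth$optode_centers[[1]][1, ])
  tpl <- svo$video$frames[(ctr[1] - 14):(ctr[1] + 15) + 1,
                          (ctr[2] - 19):(ctr[2] + 20) + 1, 1]
  expect_lt(max(ncc_fft(tpl, svo$video$frames[, , 2])), 0.995)
  expect_gt(max(ncc_fft(tpl, svo$video$frames[, , 3])), 0.995)

  expect_error(synth_thermal_video(2, c(80, 100),
                                   trajectory = matrix(c(0, 60, 0, 0), 2, 2)),
               "outside the frame")
})

test_that("generators are pure functions of seed and parameters", {
  a <- synth_thermal_video(2, c(60, 80), seed = 5)
  b <- synth_thermal_video(2, c(60, 80), seed = 5)
  expect_identical(a$video$frames, b$video$frames)
  # and they do not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(synth_resting_fnirs(10, 60, 1, seed = 3))
  expect_identical(rnorm(1), before)
})
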