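fs <- 10

# hand-built tiny grids for mask enumeration
fake_scalogram <- function(mag, freqs) {
  structure(list(coefficients = mag + 0i, frequencies = freqs, fs = fs,
                 params = wavelet_params(), signal_mean = 0,
                 n = ncol(mag)), class = "scalogram")
}
fake_coherence <- function(vals, freqs) {
  structure(list(values = vals, frequencies = freqs, fs = fs,
                 params = wavelet_params()), class = "coherence_map")
}

test_that("mask construction matches hand enumeration for both rules", {
  freqs <- c(2, 1, 0.5, 0.25)
  M <- rbind(c(1.0, 0.2, 0.0, 0.9),
             c(0.7, 0.7, 0.1, 0.0),
             c(0.0, 0.5, 0.8, 0.3),
             c(0.2, 0.0, 0.0, 0.65))          # already max-normalized
  C <- rbind(c(0.9, 0.9, 0.1, 0.2),
             c(0.1, 0.8, 0.9, 0.9),
             c(0.0, 0.7, 0.5, 0.9),
             c(0.9, 0.1, 0.0, 0.7))
  sc <- fake_scalogram(M, freqs)
  ch <- fake_coherence(C, freqs)

  # hand enumeration at T = 0.6: cells with M > .6: (1,1),(1,4),(2,1),(2,2),
  # (3,3),(4,4); cells with C > .6: (1,1),(1,2),(2,2),(2,3),(2,4),(3,2),
  # (3,4),(4,1),(4,4)
  both <- matrix(FALSE, 4, 4); both[1, 1] <- both[2, 2] <- both[4, 4] <- TRUE
  expect_identical(build_mask(sc, ch, correction_config(0.6)), both)

  either <- matrix(FALSE, 4, 4)
  either[cbind(c(1, 1, 2, 2, 3, 4, 1, 2, 2, 3, 3, 4),
               c(1, 4, 1, 2, 3, 4, 2, 3, 4, 2, 4, 1))] <- TRUE
  expect_identical(build_mask(sc, ch, correction_config(0.6, "union")), either)

  # T above both bounds: empty regardless of rule
  expect_false(any(build_mask(sc, ch, correction_config(1.5))))
  expect_false(any(build_mask(sc, ch, correction_config(1.5, "union"))))

  # all-zero motion: nothing to exclude
  z <- fake_scalogram(matrix(0, 4, 4), freqs)
  expect_false(any(build_mask(z, ch, correction_config(0.4, "union"))))

  bad <- fake_coherence(C[1:3, ], freqs[1:3])
  expect_error(build_mask(sc, bad, correction_config()), "congruent")
})

test_that("raising the threshold only shrinks the mask", {
  set.seed(2)
  n <- 1200
  sig <- synth_resting_fnirs(fs, n / fs, 1, seed = 2)$data[1, ]
  ev <- motion_events(c(40, 80), c("spike", "shift"), c(5, 4), c(0.3, 0.2))
  mo <- synth_motion_trace(ev, fs, n / fs)
  msc <- cwt_morse(mo$values, fs)
  coh <- wcoh_morlet(sig, mo$values, fs)
  prev <- NULL
  for (T in c(0.4, 0.5, 0.6, 0.7, 0.8)) {
    m <- build_mask(msc, coh, correction_config(T))
    if (!is.null(prev)) expect_true(all(prev | !m))   # m subset of prev
    prev <- m
  }
})

test_that("zero motion produces an empty mask and leaves the signal intact", {
  set.seed(3)
  n <- 1500
  x <- synth_resting_fnirs(fs, n / fs, 1, seed = 3)$data[1, ]
  res <- correct_channel(x, motion_trace(rep(0, n), fs))
  expect_equal(res$mask_occupancy, 0)
  expect_equal(res$corrected, x, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("correction attenuates motion-coupled spikes and steps", {
  dur <- 200; n <- dur * fs
  clean <- synth_resting_fnirs(fs, dur, 1, seed = 8)
  ev <- motion_events(c(60, 61.5, 100, 140), c("spike", "spike", "shift", "spike"),
                      c(6, 4, 5, 7), c(0.3, -0.25, 0.2, 0.35))
  mo <- synth_motion_trace(ev, fs, dur)
  bad <- inject_motion_artifacts(clean, mo, ev)
  res <- correct_channel(bad$recording$data[1, ], mo)
  mse_bad <- mse_metric(bad$recording$data[1, ], clean$data[1, ])
  mse_cor <- mse_metric(res$corrected, clean$data[1, ])
  expect_lt(mse_cor, mse_bad)

  # the persistent step is reduced: before/after means around the shift
  pre <- (95 * fs):(99 * fs); post <- (101 * fs):(105 * fs)
  step_bad <- abs(mean(bad$recording$data[1, post]) -
                  mean(bad$recording$data[1, pre]))
  step_cor <- abs(mean(res$corrected[post]) - mean(res$corrected[pre]))
  expect_lt(step_cor, step_bad)
})

test_that("recording-level correction shares motion scalograms per detector", {
  dur <- 120; n <- dur * fs
  rec <- synth_resting_fnirs(fs, dur, 8, seed = 4)   # 2 detectors, 4 + 4
  ev <- motion_events(60, "spike", 5, 0.3)
  mo <- synth_motion_trace(ev, fs, dur)
  traces <- list(det1 = mo, det2 = mo)
  res <- correct_recording(rec, traces)
  expect_identical(res$n_motion_scalograms, 2L)
  expect_length(res$mask_occupancy, 8)
  expect_identical(dim(res$corrected$data), dim(rec$data))

  # purity: identical channels give identical corrected outputs
  twin <- fnirs_recording(rec$data[c(1, 1), ], fs, detector = c("det1", "det1"))
  rtwin <- correct_recording(twin, traces["det1"])
  expect_identical(rtwin$corrected$data[1, ], rtwin$corrected$data[2, ])

  # all-zero traces: every channel passes through unchanged
  z <- motion_trace(rep(0, n), fs)
  rz <- correct_recording(rec, list(det1 = z, det2 = z))
  expect_equal(rz$corrected$data, rec$data, tolerance = 1e-12)

  expect_error(correct_recording(rec, list(det1 = mo)), "det2")
})

test_that("repeated correction does not erode the signal", {
  dur <- 150
  clean <- synth_resting_fnirs(fs, dur, 1, seed = 12)
  ev <- motion_events(c(50, 90), c("spike", "shift"), c(6, 4), c(0.3, 0.2))
  mo <- synth_motion_trace(ev, fs, dur)
  bad <- inject_motion_artifacts(clean, mo, ev)
  once <- correct_channel(bad$recording$data[1, ], mo)$corrected
  twice <- correct_channel(once, mo)$corrected
  int <- 101:(dur * fs - 100)
  rel <- sqrt(mean((twice[int] - once[int])^2)) / sd(once[int])
  expect_lt(rel, 0.05)
})

test_that("misaligned or gapped motion input is rejected", {
  x <- rnorm(500)
  expect_error(correct_channel(x, motion_trace(rep(0, 400), fs)), "length")
  gap <- rep(0.5, 500); gap[10] <- NA
  expect_error(correct_channel(x, structure(list(values = gap, fs = fs),
                                            class = "motion_trace")),
               "gap")
})
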