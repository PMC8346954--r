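test_that("Otsu threshold maximizes between-class variance", {
  half <- matrix(c(rep(23, 128), rep(34, 128)), 16, 16)
  seg <- otsu_segment(half)
  expect_gt(seg$threshold, 23)
  expect_lt(seg$threshold, 34)
  expect_identical(seg$skin_mask, half == 34)

  # brute-force oracle over all 256 split points, random bimodal frames
  set.seed(42)
  for (i in 1:5) {
    fr <- matrix(c(rnorm(100, 24, 0.8), rnorm(156, 33, 1.2)), 16, 16)
    expect_equal(otsu_segment(fr)$threshold, otsu_exhaustive(fr))
  }
  expect_error(otsu_segment(matrix(5, 4, 4)), "constant")
})

test_that("Gaussian pyramid halves dimensions and preserves DC", {
  img <- matrix(rnorm(240 * 320), 240, 320)
  expect_identical(dim(gaussian_pyramid(img, 1)), c(120L, 160L))
  expect_identical(gaussian_pyramid(img, 0), img)
  expect_identical(dim(gaussian_pyramid(matrix(0, 9, 13), 1)), c(5L, 7L))

  const <- matrix(3.7, 64, 64)
  out <- gaussian_pyramid(const, 2)
  expect_identical(dim(out), c(16L, 16L))
  expect_lt(max(abs(out - 3.7)), 1e-9)

  expect_error(gaussian_pyramid(matrix(1:2, 1, 2), 1), "small")
})

test_that("FFT NCC equals spatial NCC and is mean/self consistent", {
  set.seed(7)
  img <- matrix(rnorm(32 * 32), 32, 32)
  tpl <- img[10:17, 5:12]
  surf <- ncc_fft(tpl, img)
  expect_equal(dim(surf), c(25L, 25L))
  expect_equal(surf[10, 5], 1.0, tolerance = 1e-9)       # self-match
  expect_equal(unname(arrayInd(which.max(surf), dim(surf))[1, ]), c(10L, 5L))
  expect_equal(max(ncc_fft(tpl, img + 5)), 1.0, tolerance = 1e-9)  # mean-invariant

  expect_lt(max(abs(surf - ncc_spatial(tpl, img))), 1e-8)  # oracle equivalence

  expect_error(ncc_fft(matrix(1, 4, 4), img), "variance")
  expect_error(ncc_fft(matrix(rnorm(50^2), 50, 50), img), "larger")
})

test_that("tracker recovers a known trajectory and flags occlusions", {
  sv <- make_tracking_video(50, c(120, 160), occ = c(20, 33), seed = 6)
  tr <- track_mroi(sv$video, detector_roi(sv))

  expect_identical(which(!is.finite(tr$mroi_centers[, 1])), c(20L, 33L))
  expect_identical(tr$n_discarded, 2L)
  ok <- is.finite(tr$mroi_centers[, 1])
  truth <- sv$truth$optode_centers[[1]]
  expect_lt(max(abs(tr$mroi_centers[ok, ] - truth[ok, ])), 2)
  g <- tr$gamma[ok]
  expect_true(all(g > 0.995) && all(g <= 1 + 1e-12))
})

test_that("static noise-free video tracks with gamma exactly 1", {
  sv <- synth_thermal_video(4, c(100, 120), noise_sd = 0, seed = 1)
  tr <- track_mroi(sv$video, detector_roi(sv))
  expect_equal(tr$gamma, rep(1, 4), tolerance = 1e-9)
  expect_true(all(tr$mroi_centers == matrix(tr$mroi_centers[1, ], 4, 2,
                                            byrow = TRUE)))
})

test_that("tracking is translation-equivariant", {
  base <- matrix(0, 20, 2)
  shifted <- base + matrix(c(4, 6), 20, 2, byrow = TRUE)
  a <- synth_thermal_video(20, c(120, 160), base, seed = 3)
  b <- synth_thermal_video(20, c(120, 160), shifted, seed = 3)
  ra <- track_mroi(a$video, detector_roi(a))
  rb <- track_mroi(b$video, detector_roi(b))
  d <- rb$mroi_centers - ra$mroi_centers
  expect_lt(max(abs(d[, 1] - 4)), 2 + 1e-9)
  expect_lt(max(abs(d[, 2] - 6)), 2 + 1e-9)
})

test_that("noise degrades the matching correlation on average", {
  traj <- cbind(even_walk(8, 6, 1), even_walk(8, 6, 2))
  gmean <- sapply(c(0, 0.2), function(sdn) {
    mean(sapply(1:4, function(s) {
      sv <- synth_thermal_video(8, c(100, 120), traj, noise_sd = sdn,
                                seed = s)
      tr <- track_mroi(sv$video, detector_roi(sv, gamma_th = 0.5))
      mean(tr$gamma, na.rm = TRUE)
    }))
  })
  expect_gt(gmean[1], gmean[2])
})

test_that("slave ROIs ride rigidly on the master ROI", {
  sv <- make_tracking_video(15, c(120, 160), seed = 9)
  roi <- detector_roi(sv, srois = list(list(offset = c(10, -8),
                                            semi_axes = c(4, 6))))
  tr <- track_mroi(sv$video, roi)
  off <- tr$sroi_centers[[1]] - tr$mroi_centers
  ok <- is.finite(off[, 1])
  expect_true(all(abs(off[ok, 1] - 10) < 1e-9))
  expect_true(all(abs(off[ok, 2] + 8) < 1e-9))
})

test_that("resultant motion combines axes, interpolates gaps, resamples", {
  tr <- structure(list(
    mroi_centers = rbind(c(0, 0), c(3, 4), c(NaN, NaN), c(6, 8)),
    gamma = c(1, 1, NA, 1), sroi_centers = list(), n_discarded = 1L,
    roi = roi_spec(c(0, 0), 4, 4), fs = 10), class = "track_result")
  mt <- resultant_motion(tr)
  expect_equal(mt$values, c(0, 5, 7.5, 10))   # 3-4-5 triangle; linear gap fill
  expect_identical(mt$interpolated, c(FALSE, FALSE, TRUE, FALSE))

  half <- resultant_motion(tr, target_fs = 5)
  expect_length(half$values, 2)

  allnan <- tr
  allnan$mroi_centers[] <- NaN
  expect_error(resultant_motion(allnan), "retained")
})
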