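fs <- 10

test_that("GLM fit matches the closed-form OLS oracle", {
  # exact fit: signal = 2 * regressor
  reg <- activation_regressor(paradigm(c(10, 40), 10, 80), fs)
  g <- glm_hrf(2 * reg, reg)
  expect_equal(g$beta, 2)
  expect_equal(g$residual_sd, 0)

  # orthogonal to the centered regressor: beta = 0
  rc <- reg - mean(reg)
  orth <- rnorm(length(reg))
  orth <- orth - mean(orth)
  orth <- orth - sum(orth * rc) / sum(rc^2) * rc
  expect_lt(abs(glm_hrf(orth, reg)$beta), 1e-10)

  # n = 6 hand-solvable case against explicit normal equations
  x <- c(0, 1, 2, 1, 0, 0.5)
  y <- c(0.3, 1.8, 4.2, 2.1, 0.1, 1.4)
  X <- cbind(x, 1)
  bh <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% bh
  s2 <- sum(r^2) / (6 - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[1, 1])
  g6 <- glm_hrf(y, x)
  expect_equal(g6$beta, bh[1], tolerance = 1e-10)
  expect_equal(g6$t_stat, bh[1] / se, tolerance = 1e-10)

  expect_error(glm_hrf(y, rep(1, 6)), "constant")
})

test_that("SNR is beta over resting SD and scale-invariant", {
  g <- structure(list(beta = 2, beta_se = 0.1, t_stat = 20,
                      residual_sd = 1, sigma_rest = 0.5), class = "hrf_glm")
  expect_equal(snr_metric(g), 4)
  g$beta <- 0
  expect_equal(snr_metric(g), 0)
  g$sigma_rest <- 0
  expect_error(snr_metric(g), "sigma_rest")

  # scaling the whole signal rescales beta and sigma_rest alike
  reg <- activation_regressor(paradigm(c(20, 60), 15, 100), fs)
  rest <- make_boxcar(paradigm(c(20, 60), 15, 100), fs) == 0
  set.seed(2)
  sig <- 0.5 * reg + rnorm(length(reg), 0, 0.3)
  s1 <- snr_metric(glm_hrf(sig, reg, rest))
  s2 <- snr_metric(glm_hrf(7 * sig, reg, rest))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("MSE is the plain mean of squared differences", {
  expect_equal(mse_metric(1:5, 1:5), 0)
  expect_equal(mse_metric(rep(2.5, 10), rep(1, 10)), 1.5^2)
  a <- c(0.3, -1, 2, 0.7, 5)
  b <- c(1, 0, 2, -0.3, 4.5)
  expect_equal(mse_metric(a, b),
               (0.7^2 + 1 + 0 + 1^2 + 0.5^2) / 5)
})

test_that("paired t test matches the closed form and the 8-channel design", {
  r <- paired_ttest(c(1, 2, 3, 4), c(2, 3, 5, 7))
  d <- c(-1, -1, -2, -3)
  expect_equal(r$t, mean(d) / (sd(d) / 2), tolerance = 1e-10)
  expect_equal(r$t, -3.6556, tolerance = 1e-4)
  expect_identical(r$df, 3L)

  # cross-check p-value against stats::t.test
  set.seed(6)
  a <- rnorm(8); b <- rnorm(8)
  mine <- paired_ttest(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_identical(mine$df, 7L)             # 8 channels -> df 7

  expect_error(paired_ttest(a, a + 3), "zero-variance")
})

test_that("benchmark subjects are reproducible with exact ground truth", {
  cfg <- tiny_bench(seed = 21)
  s1 <- simulate_subject(cfg, 1)
  s2 <- simulate_subject(cfg, 1)
  expect_identical(s1$corrupted$data, s2$corrupted$data)
  expect_identical(s1$trace$values, s2$trace$values)

  # corrupted - clean is exactly the injected artifact series
  art <- s1$corrupted$data - s1$clean$data
  expect_true(all(abs(art[, s1$trace$values < 1e-3 &
                           seq_along(s1$trace$values) < 150]) < 1e-9))
  expect_gt(max(abs(art)), 0.1)
})

test_that("fitted beta recovers the injected amplitude within 3 SE", {
  # OLS coverage is exact under white noise; the vignette documents why
  # slow physiological drift biases the single-regressor GLM instead
  fs <- 10
  p <- paradigm(seq(20, 160, 40), 20, 200)
  reg <- activation_regressor(p, fs)
  A <- 0.5
  hits <- 0
  set.seed(31)
  for (r in 1:40) {
    sig <- A * reg + rnorm(length(reg), 0, 0.3)
    g <- glm_hrf(sig, reg)
    if (abs(g$beta - A) <= 3 * g$beta_se) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("method comparison reproduces the paired design over channels", {
  cfg <- benchmark_config(n_replicates = 1, seed = 41)
  cmp <- compare_methods(cfg, methods = c("none", "proposed", "wavelet"))
  expect_true(all(cmp$ttests$df == cfg$n_channels - 1))
  expect_setequal(unique(cmp$metrics$method), c("none", "proposed", "wavelet"))

  # direction: corrupted channels get closer to the clean ground truth
  # (the SNR direction needs a full-size sample and is checked end to end)
  cm <- cmp$channel_means
  mse_prop <- mean(cm$mse[cm$method == "proposed"])
  mse_none <- mean(cm$mse[cm$method == "none"])
  expect_lt(mse_prop, mse_none)

  # self-comparison has zero-variance differences: reported non-applicable
  self <- cmp$ttests[cmp$ttests$comparison == "proposed vs proposed", ]
  expect_true(nrow(self) > 0 && all(is.na(self$t)) && all(is.na(self$p)))
})
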