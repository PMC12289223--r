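test_that("uniform resampling is exact on-grid and detrends linearly", {
  cfg <- spectralConfig()
  t <- seq(0, 59.75, by = 0.25)
  v <- sin(seq_along(t))
  u <- toUniformSeries(t, v, cfg, detrend = FALSE)
  expect_true(u$ok)
  expect_equal(u$x, v)
  # linear series vanish after first-order detrend
  u <- toUniformSeries(t, 3 + 0.2 * t, cfg)
  expect_lt(max(abs(u$x)), 1e-9)
  # 0.1 Hz beat series: spectral peak at 0.1 Hz after resampling
  tb <- cumsum(rep(0.8, 150)); tb <- tb - tb[1]
  vb <- sin(2 * pi * 0.1 * tb)
  u <- toUniformSeries(tb, vb, cfg)
  sp <- Mod(stats::fft(u$x))^2
  f <- (seq_along(sp) - 1) / length(sp) * 4
  half <- f <= 2 & f > 0
  expect_equal(f[half][which.max(sp[half])], 0.1, tolerance = 0.02)
  # gap and length rejections
  expect_equal(toUniformSeries(c(0, 10, 20), c(1, 2, 3), cfg)$reason, "gap")
  expect_equal(toUniformSeries(c(0, 1, 2), c(1, 2, 3), cfg)$reason,
               "too_short")
})

test_that("Welch estimator matches the direct-DFT brute-force oracle", {
  set.seed(42)
  x <- rnorm(480)
  y <- stats::filter(x, c(0.7, 0.3), sides = 1)
  y[is.na(y)] <- 0
  y <- as.numeric(y) + 0.3 * rnorm(480)
  est <- estimateTransfer(x, y)
  orc <- oracleWelch(x, y)
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-300))
  expect_lt(rel(est@Pxx, orc$Pxx), 1e-10)
  expect_lt(rel(est@Pyy, orc$Pyy), 1e-10)
  expect_lt(max(Mod(est@Pxy - orc$Pxy) / pmax(Mod(orc$Pxy), 1e-300)), 1e-10)
  expect_lt(rel(gain(est), orc$gain), 1e-10)
  expect_lt(rel(coherence(est), orc$msc), 1e-10)
  expect_error(estimateTransfer(rnorm(200), rnorm(199)), "equal length")
  expect_error(estimateTransfer(rnorm(10), rnorm(10)), "shorter")
})

test_that("an exact linear relation gives gain 2 and unit coherence", {
  set.seed(7)
  x <- rnorm(600)
  est <- estimateTransfer(x, 2 * x)
  cfg <- spectralConfig()
  sel <- est@f >= cfg$lf_band[1] & est@f <= cfg$lf_band[2]
  expect_true(any(sel))
  expect_lt(max(abs(gain(est)[sel] - 2)), 1e-6)
  expect_gte(min(coherence(est)[sel]), 0.999)
  idx <- brsIndex(est, cfg)
  expect_equal(brsValue(idx), 2, tolerance = 1e-6)
  expect_true(qualified(idx))
})

test_that("coherence bias for independent noise shrinks with segments", {
  msc_mean <- function(n, nseeds = 100) {
    mean(vapply(seq_len(nseeds), function(s) {
      set.seed(s)
      est <- estimateTransfer(rnorm(n), rnorm(n))
      mean(coherence(est))
    }, numeric(1)))
  }
  m7 <- msc_mean(480)    # 7 Welch segments
  m31 <- msc_mean(1920)  # 31 segments
  expect_gt(m7, m31)
  expect_lt(m31, 0.1)
  expect_lt(m7, 0.35)
})

test_that("BRS scale covariance and msc invariance hold", {
  set.seed(3)
  x <- rnorm(480); y <- as.numeric(stats::filter(x, 0.9, "recursive")) +
    0.5 * rnorm(480)
  cfg <- spectralConfig()
  v0 <- brsIndex(estimateTransfer(x, y), cfg)
  vx <- brsIndex(estimateTransfer(4 * x, y), cfg)
  vy <- brsIndex(estimateTransfer(x, 4 * y), cfg)
  expect_equal(vx@value, v0@value / 4, tolerance = 1e-12)
  expect_equal(vy@value, v0@value * 4, tolerance = 1e-12)
  expect_equal(vx@meanLFCoherence, v0@meanLFCoherence, tolerance = 1e-12)
  expect_equal(vy@meanLFCoherence, v0@meanLFCoherence, tolerance = 1e-12)
})

test_that("adding output noise never raises mean coherence (over seeds)", {
  diffs <- vapply(1:25, function(s) {
    set.seed(s)
    x <- rnorm(480)
    y <- as.numeric(stats::filter(x, c(0.6, 0.4), sides = 1))
    y[is.na(y)] <- 0
    m0 <- mean(coherence(estimateTransfer(x, y)))
    m1 <- mean(coherence(estimateTransfer(x, y + rnorm(480))))
    m1 - m0
  }, numeric(1))
  expect_lt(mean(diffs), 0)
  expect_gt(mean(diffs < 0), 0.9)
})

test_that("msc stays within [0, 1] for adversarial inputs", {
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(240) * 10^runif(1, -8, 8)
    y <- x * runif(1, -2, 2) + rnorm(240) * 10^runif(1, -8, 8)
    est <- estimateTransfer(x, y)
    expect_true(all(est@msc >= 0 & est@msc <= 1))
  }
  # constant input: Pxx = 0 handled
  est <- estimateTransfer(rep(1, 240), rnorm(240))
  expect_true(all(is.finite(est@msc)))
})

test_that("HRV band powers follow Parseval for pure tones", {
  cfg <- spectralConfig()
  tt <- seq(0, 300, by = 0.25)
  A <- 40
  lf_tone <- A * sin(2 * pi * 0.1 * tt)
  expect_equal(hrvBandPower(lf_tone, "lf", cfg), A^2 / 2, tolerance = 0.05)
  expect_lt(hrvBandPower(lf_tone, "hf", cfg), 0.01 * A^2 / 2)
  hf_tone <- A * sin(2 * pi * 0.25 * tt)
  expect_equal(hrvBandPower(hf_tone, "hf", cfg), A^2 / 2, tolerance = 0.05)
  expect_lt(hrvBandPower(hf_tone, "lf", cfg),
            0.05 * hrvBandPower(hf_tone, "hf", cfg))
})

test_that("white-noise LF/HF ratio matches the band bin counts", {
  cfg <- spectralConfig()
  f <- (0:(cfg$segment_len %/% 2)) * cfg$resample_fs / cfg$segment_len
  nlf <- sum(f >= 0.04 & f <= 0.15 & f > 0)
  nhf <- sum(f > 0.15 & f <= 0.40)
  ratios <- vapply(1:100, function(s) {
    set.seed(s)
    rr <- rnorm(960, sd = 30)
    hrvBandPower(rr, "lf", cfg) / hrvBandPower(rr, "hf", cfg)
  }, numeric(1))
  expect_equal(mean(ratios), nlf / nhf, tolerance = 0.1)
})

test_that("the LF band must be resolvable", {
  cfg <- spectralConfig(segment_len = 16)
  set.seed(1)
  est <- estimateTransfer(rnorm(64), rnorm(64), cfg)
  expect_error(brsIndex(est, cfg), "band_unresolved")
})
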