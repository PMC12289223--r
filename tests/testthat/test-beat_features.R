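test_that("RR intervals follow their definition", {
  expect_equal(computeRR(c(0, 1, 2)), c(1000, 1000))
  expect_equal(computeRR(c(0, 0.8, 1.7)), c(800, 900))
  expect_length(computeRR(5), 0L)
})

test_that("PAT pairing picks the first in-window upstroke", {
  p <- computePAT(c(10, 11), c(10.25, 11.30))
  expect_equal(p$pat[1], 250)
  # upstroke after the 80% RR window: unpaired
  p <- computePAT(c(10, 11), c(10.95))
  expect_true(is.na(p$pat[1]))
  expect_equal(p$reason[1], "unpaired")
  # R with no upstroke before next R
  p <- computePAT(c(10, 11, 12), c(10.2, 12.2))
  expect_true(is.na(p$pat[2]))
})

test_that("RDRatio matches exact geometry on piecewise-linear pulses", {
  fs <- 1000
  # symmetric triangle: ratio exactly 1
  up <- seq(0, 1, length.out = 201)
  tri <- c(up, rev(up)[-1])
  fid <- data.frame(foot_i = 1L, peak_i = 201L, beat_end_i = 401L)
  expect_equal(computeRDRatio(tri, fs, fid)$rdratio, 1, tolerance = 1e-9)
  # 100 ms linear rise, 300 ms linear decay: 60 / 180 = 1/3
  rise <- seq(0, 1, length.out = 101)              # 100 ms at 1 kHz
  decay <- seq(1, 0, length.out = 301)[-1]         # 300 ms
  fid <- data.frame(foot_i = 1L, peak_i = 101L, beat_end_i = 401L)
  expect_equal(computeRDRatio(c(rise, decay), fs, fid)$rdratio, 1 / 3,
               tolerance = 1e-9)
})

test_that("RDRatio agrees with a dense-grid threshold-scan oracle", {
  # gamma-shaped pulse
  fun <- function(t) stats::dgamma(t, shape = 3, rate = 12) /
    max(stats::dgamma(seq(0, 1, 1e-4), shape = 3, rate = 12))
  expected <- oracleRDRatio(fun, 1.2)
  fs <- 240
  tt <- seq(0, 1.2, by = 1 / fs)
  x <- fun(tt)
  fid <- data.frame(foot_i = 1L, peak_i = which.max(x),
                    beat_end_i = length(x))
  got <- computeRDRatio(x, fs, fid)$rdratio
  expect_equal(got, expected, tolerance = 0.01)
})

test_that("RDRatio flags limbs without a crossing", {
  x <- c(0, 0.5, 1, 0.9, 0.8, 0.75)  # decay never reaches 10%
  fid <- data.frame(foot_i = 1L, peak_i = 3L, beat_end_i = 6L)
  r <- computeRDRatio(x, 100, fid)
  expect_true(is.na(r$rdratio))
  expect_equal(r$reason, "no_crossing")
})

test_that("amplitude features are homogeneous, time features invariant", {
  fs <- 240
  feet <- seq(0.5, 7.5, by = 1)
  sig <- pulseTrain(feet, fs, 8.2)
  fid <- detectPulseFiducials(sig, fs)
  filt <- preprocessSignal(sig, fs)$filtered
  a1 <- computeAmplitudeFeatures(filt, fid)
  r1 <- computeRDRatio(filt, fs, fid)$rdratio
  c_ <- 2.5
  fid2 <- detectPulseFiducials(c_ * sig, fs)
  filt2 <- preprocessSignal(c_ * sig, fs)$filtered
  a2 <- computeAmplitudeFeatures(filt2, fid2)
  r2 <- computeRDRatio(filt2, fs, fid2)$rdratio
  expect_equal(a2$PeakAmp, c_ * a1$PeakAmp, tolerance = 1e-8)
  expect_equal(a2$Upstroke, c_ * a1$Upstroke, tolerance = 1e-8)
  expect_equal(r2, r1, tolerance = 1e-8)
  # pressure channel: PeakAmp is the absolute systolic value
  ap <- computeAmplitudeFeatures(filt + 80, fid, pressure = TRUE)
  expect_equal(ap$SBP, ap$PeakAmp)
  expect_gt(min(ap$SBP, na.rm = TRUE), 80)
})

test_that("beat tables conserve one slot per detected beat", {
  cfg <- simConfig(duration_s = 40, seed = 12)
  gt <- simulateBeats(cfg)
  rec <- renderSignals(gt, cfg, channels = c("ECG", "PPG"), noise = FALSE)
  bt <- beatTable(rec, "PPG")
  rp <- detectRPeaks(channel(rec, "ECG"), cfg$fs)
  expect_equal(nBeats(bt), length(rp))
  b <- beats(bt)
  for (col in c("RR", "PAT", "PeakAmp", "Upstroke", "RDRatio"))
    expect_length(b[[col]], length(rp))
  # every row is either valued or reason-flagged for PAT
  expect_true(all(!is.na(b$PAT) | lengths(reasons(bt)) > 0))
})

test_that("beat features recover simulator ground truth on noiseless renderings", {
  cfg <- simConfig(duration_s = 60, fs = 240, seed = 2, rr_noise_sd_ms = 0,
                   pat_noise_sd_ms = 0, rdr_noise_sd = 0, sbp_noise_sd = 0)
  gt <- simulateBeats(cfg)
  g <- groundTruth(gt)
  rec <- renderSignals(gt, cfg, channels = c("ECG", "PPG"), noise = FALSE)
  b <- beats(beatTable(rec, "PPG"))
  expect_equal(nrow(b), nrow(g))
  inner <- 2:(nrow(b) - 2)           # boundary beats clipped by the record
  expect_lt(max(abs(b$RR - g$rr)[inner]), 1000 / cfg$fs + 1e-6)
  ok <- inner[!is.na(b$PAT[inner])]
  expect_gt(length(ok), 0.9 * length(inner))
  expect_lt(max(abs(b$PAT - g$pat)[ok]), 1000 / cfg$fs + 1e-6)
  ok <- inner[!is.na(b$RDRatio[inner])]
  expect_lt(max(abs(b$RDRatio / g$rdr - 1)[ok]), 0.02)
})
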