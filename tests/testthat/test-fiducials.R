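test_that("preprocessing yields the expected derivative on simple shapes", {
  fs <- 240
  n <- 2400
  # constant
  p <- preprocessSignal(rep(5, n), fs)
  expect_lt(max(abs(p$derivative)), 1e-8)
  # ramp of slope 3 units/s: interior derivative ~ 3
  p <- preprocessSignal(3 * (seq_len(n) - 1) / fs, fs)
  interior <- 200:(n - 200)
  expect_lt(max(abs(p$derivative[interior] - 3)), 1e-3)
  expect_length(p$filtered, n)
  expect_error(preprocessSignal(rnorm(100), fs = 20), "exceed 20 Hz")
})

test_that("20 Hz attenuation matches the designed filter response", {
  fs <- 240
  tt <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 20 * tt)
  filt <- preprocessSignal(x, fs)$filtered
  interior <- 500:(length(x) - 500)
  measured <- max(abs(filt[interior]))
  # analytic: evaluate the designed transfer polynomial at z = e^{-jw};
  # forward-backward application squares the magnitude response
  bf <- signal::butter(4, 10 / (fs / 2), type = "low")
  w <- 2 * pi * 20 / fs
  z <- exp(-1i * w * (seq_along(bf$b) - 1))
  H <- sum(bf$b * z) / sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1)))
  expect_equal(measured, Mod(H)^2, tolerance = 0.02)
})

test_that("R-peak detection recovers constructed and simulated beats", {
  fs <- 240
  # 60 bpm for 60 s -> 60 peaks at 1.0 s spacing (edge beats clipped at
  # the record boundary are allowed 1 extra sample of slack)
  rt <- seq(0.5, 59.5, by = 1)
  ecg <- syntheticECG(rt, fs, 60)
  rp <- detectRPeaks(ecg, fs)
  expect_length(rp, 60L)
  expect_lt(max(abs(rp - rt)), 1 / fs + 1e-9)
  expect_lt(max(abs(diff(rp) - 1)), 2 / fs)
  # flatline: empty with a warning, not an error
  expect_warning(rp0 <- detectRPeaks(rep(0.3, fs * 5), fs), "no R-peaks")
  expect_length(rp0, 0L)
  # simulator with known RR series
  cfg <- simConfig(duration_s = 60, seed = 5)
  gt <- simulateBeats(cfg)
  rec <- renderSignals(gt, cfg, channels = "ECG", noise = FALSE)
  rp <- detectRPeaks(channel(rec, "ECG"), cfg$fs)
  expect_length(rp, nBeats(gt))
  inner <- 2:(length(rp) - 1)
  expect_lt(max(abs(rp[inner] - gt@t[inner])), 1 / cfg$fs + 1e-9)
  rr <- computeRR(rp)
  expect_lt(max(abs(rr[inner] - gt@rr[inner])), 1000 / cfg$fs + 1e-6)
})

test_that("pulse upstroke sits at the derivative argmax of the beat", {
  fs <- 240
  feet <- seq(0.5, 9.5, by = 1)
  sig <- pulseTrain(feet, fs, 10.5)
  fid <- detectPulseFiducials(sig, fs)
  expect_gt(nrow(fid), 5)
  # brute-force scan: finite-difference derivative argmax per beat
  d <- diff(sig) * fs
  tt <- (seq_along(d) - 0.5) / fs
  for (k in seq_len(nrow(fid))) {
    sel <- tt > fid$foot_t[k] & tt < fid$peak_t[k]
    expect_lt(abs(tt[sel][which.max(d[sel])] - fid$upstroke_t[k]), 1.5 / fs)
  }
  # fiducial ordering invariant
  expect_true(all(fid$foot_t <= fid$upstroke_t))
  expect_true(all(fid$upstroke_t <= fid$peak_t))
  expect_true(all(is.na(fid$notch_t) | fid$peak_t <= fid$notch_t))
  expect_true(all(is.na(fid$secondary_peak_t) | is.na(fid$notch_t) |
                    fid$notch_t <= fid$secondary_peak_t))
})

test_that("fiducials are translation-equivariant and amplitude-invariant", {
  fs <- 240
  feet <- seq(0.5, 9.5, by = 1)
  sig <- pulseTrain(feet, fs, 10.5)
  fid <- detectPulseFiducials(sig, fs)
  # shift by k samples
  k <- 24L
  sigs <- c(rep(0, k), sig)[seq_along(sig)]
  fids <- detectPulseFiducials(sigs, fs)
  m <- min(nrow(fid) - 1L, nrow(fids))
  expect_equal(fids$upstroke_t[1:m], fid$upstroke_t[1:m] + k / fs,
               tolerance = 1e-9)
  expect_equal(fids$peak_t[1:m], fid$peak_t[1:m] + k / fs,
               tolerance = 1e-9)
  # amplitude scaling: times unchanged, slope scales
  fidc <- detectPulseFiducials(3.7 * sig, fs)
  expect_equal(fidc$upstroke_t, fid$upstroke_t)
  expect_equal(fidc$foot_t, fid$foot_t)
  expect_equal(fidc$upstroke_slope, 3.7 * fid$upstroke_slope,
               tolerance = 1e-9)
})

test_that("beat count matches ground truth on noiseless renderings", {
  cfg <- simConfig(duration_s = 45, seed = 9)
  gt <- simulateBeats(cfg)
  rec <- renderSignals(gt, cfg, channels = c("ECG", "PPG"), noise = FALSE)
  rp <- detectRPeaks(channel(rec, "ECG"), cfg$fs)
  expect_length(rp, nBeats(gt))
})
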