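test_that("the generator is deterministic and obeys its couplings", {
  cfg <- simConfig(duration_s = 120, seed = 77)
  g1 <- simulateBeats(cfg)
  g2 <- simulateBeats(cfg)
  expect_identical(groundTruth(g1), groundTruth(g2))
  # pre-noise series satisfy the linear couplings exactly
  g <- groundTruth(g1)
  expect_equal(g$truePat, 370 - 1 * g$trueSbp, tolerance = 1e-12)
  expect_equal(g$trueRdr, 1.4 - 0.005 * g$trueSbp, tolerance = 1e-12)
})

test_that("zero-noise regression of RR on lagged SBP recovers the gain", {
  cfg <- simConfig(duration_s = 200, seed = 5, rr_noise_sd_ms = 0)
  g <- groundTruth(simulateBeats(cfg))
  n <- nrow(g)
  dev <- g$trueSbp - 120
  fit <- stats::lm(g$rr[2:n] ~ dev[1:(n - 1)])
  expect_equal(unname(coef(fit)[2]), 8, tolerance = 1e-9)
  # zero noise, zero oscillation: constant series at the baselines
  cfg0 <- simConfig(duration_s = 30, lf_amp = 0, hf_amp = 0,
                    sbp_noise_sd = 0, rr_noise_sd_ms = 0,
                    pat_noise_sd_ms = 0, rdr_noise_sd = 0)
  g0 <- groundTruth(simulateBeats(cfg0))
  expect_equal(g0$sbp, rep(120, nrow(g0)))
  expect_equal(g0$rr, rep(1000, nrow(g0)))
})

test_that("nonphysiologic configurations are rejected", {
  expect_error(simulateBeats(simConfig(duration_s = 10, rr_baseline_ms = 320,
                                       lf_amp = 20)),
               "nonphysiologic")
})

test_that("PAT is strongly anticorrelated with SBP at default noise", {
  cors <- vapply(1:10, function(s) {
    g <- groundTruth(simulateBeats(simConfig(duration_s = 300, seed = s)))
    cor(g$pat, g$sbp)
  }, numeric(1))
  expect_true(all(cors < -0.8))
})

test_that("renderings insert artifacts and cuff attenuation as scheduled", {
  cfg <- simConfig(duration_s = 120, fs = 120, seed = 3,
                   artifact_schedule = data.frame(start = 60, end = 70),
                   cuff_schedule = 20)
  gt <- simulateBeats(cfg)
  ev <- events(events(gt))
  expect_true(any(ev$kind == "cuff_inflation" & ev$start == 20))
  rec <- renderSignals(gt, cfg, channels = c("ECG", "PPG"))
  ppg <- channel(rec, "PPG")
  tt <- (seq_along(ppg) - 1) / 120
  sd_art <- sd(ppg[tt >= 61 & tt <= 69])
  sd_clean <- sd(ppg[tt >= 80 & tt <= 110])
  expect_gt(sd_art, 3 * sd_clean)
  # pulse amplitude attenuated during the occlusion
  amp_cuff <- max(ppg[tt >= 25 & tt <= 45]) - min(ppg[tt >= 25 & tt <= 45])
  expect_lt(amp_cuff, 0.5 * (max(ppg[tt >= 80 & tt <= 110]) -
                               min(ppg[tt >= 80 & tt <= 110])))
  expect_error(renderSignals(gt, simConfig(duration_s = 120, fs = 50)),
               "60 Hz")
})

test_that("the 24-h scenario schedules 80 cuff events and circadian gain", {
  sc <- scenario24h(seed = 2)
  ev <- events(events(sc$gt))
  expect_equal(sum(ev$kind == "cuff_inflation"), 80L)
  g <- groundTruth(sc$gt)
  day <- g$t < 16 * 3600 & g$t > 0
  night <- g$t >= 16 * 3600
  walk <- g$t >= 8 * 3600 & g$t < 9 * 3600
  expect_equal(mean(g$trueGain[night]) / 8, 2, tolerance = 0.02)
  expect_equal(mean(g$trueGain[walk]), 4, tolerance = 1e-9)
  # nocturnal bradycardia and SBP dip
  expect_gt(mean(g$rr[night]), mean(g$rr[day & !walk]))
  expect_lt(mean(g$sbp[night]), mean(g$sbp[day & !walk]))
})
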