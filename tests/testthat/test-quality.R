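test_that("cuff blanking spans -15/+60 s around inflation start", {
  ev <- eventList("cuff_inflation", "cuff", 100, 130)
  f <- blankCuff(c(84, 86, 100, 159, 161), ev)
  expect_equal(f, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_false(any(blankCuff(c(84, 86), eventList())))
  # overlapping windows: union
  ev2 <- eventList(rep("cuff_inflation", 2), "cuff", c(100, 140), c(130, 170))
  expect_true(all(blankCuff(seq(90, 195, by = 5), ev2)))
})

test_that("template SNR flags the noisy beat and passes clean ones", {
  fs <- 240
  feet <- seq(0.5, 10.5, by = 1)
  sig <- pulseTrain(feet, fs, 11.2)
  fid <- detectPulseFiducials(sig, fs)
  snr <- templateSNR(sig, fs, fid)
  expect_false(any(snr$flagged))
  expect_gt(median(snr$snr_db), 50)
  # corrupt one mid-record beat with strong broadband noise
  set.seed(1)
  k <- 5L
  i <- fid$foot_i[k]:fid$beat_end_i[k]
  sig2 <- sig
  sig2[i] <- sig2[i] + rnorm(length(i), 0, 1.5)
  fid2 <- detectPulseFiducials(sig, fs)  # same segmentation
  snr2 <- templateSNR(sig2, fs, fid2)
  expect_true(snr2$flagged[k])
  expect_false(any(snr2$flagged[-k]))
  # fewer than 5 beats: everything flagged, with warning
  expect_warning(few <- templateSNR(sig, fs, fid[1:3, ]), "fewer than")
  expect_true(all(few$flagged))
})

test_that("pure-noise pulse channels are overwhelmingly flagged", {
  fs <- 120
  frac <- vapply(1:20, function(s) {
    set.seed(s)
    noise <- rnorm(fs * 30)
    fid <- detectPulseFiducials(noise, fs)
    if (nrow(fid) < 5L) return(1)
    mean(suppressWarnings(templateSNR(noise, fs, fid))$flagged)
  }, numeric(1))
  expect_gte(mean(frac), 0.9)
})

test_that("PAT range filter applies the PWV-derived bounds", {
  expect_equal(patBounds(qualityConfig()), c(80, 400))
  expect_equal(patRangeFilter(c(150, 40, 450, NA)),
               c(FALSE, TRUE, TRUE, FALSE))
})

test_that("variability filter flags drastic beat-to-beat jumps only", {
  expect_false(any(variabilityFilter(rep(1000, 10))))
  f <- variabilityFilter(c(1000, 1000, 1400, 1000))
  expect_equal(f, c(FALSE, FALSE, TRUE, TRUE))  # 40% up then 29% down
  f <- variabilityFilter(c(1000, 1000, 1200, 1000))
  expect_false(any(f))                           # 20% within threshold
  expect_false(variabilityFilter(c(500, 1000, 1000))[1])  # first beat never
  # PAT jumps flag too
  f <- variabilityFilter(rep(1000, 4), c(250, 250, 400, 250))
  expect_equal(f, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("epoch qualification enforces the inclusive 50% rule", {
  t <- seq(0.5, 59.5, by = 1)  # 60 beats in epoch [0, 60)
  ok <- function(n) c(rep(TRUE, n), rep(FALSE, 60 - n))
  expect_true(all(epochQualify(t, ok(29))))   # 29/60 disqualified
  expect_false(any(epochQualify(t, ok(30))))  # exactly 50% passes
  expect_false(any(epochQualify(t, ok(60))))
})

test_that("qualification only removes beats and is idempotent", {
  bt <- regularBeats(dur = 600)
  bt@beats$PAT[c(50, 51)] <- c(40, 450)
  ev <- eventList("cuff_inflation", "", 300, 330)
  q1 <- qualifyBeats(bt, ev)
  expect_true(all(qualified(q1) <= qualified(bt)))
  q2 <- qualifyBeats(q1, ev)
  expect_equal(qualified(q2), qualified(q1))
  expect_equal(reasons(q2), reasons(q1))
  # an out-of-range PAT is also a drastic beat-to-beat change
  expect_true("pat_range" %in% reasons(q1)[[50]])
  expect_true("cuff" %in% reasons(q1)[[302]])
})

test_that("the five criteria flag exactly the constructed beats", {
  # 1 h of clean beats; one cuff event, one artifact minute (via SNR), two
  # out-of-range PAT beats, one RR jump
  bt <- regularBeats(dur = 3600)
  n <- nBeats(bt)
  t <- bt@beats$t
  bt@beats$PAT[c(500, 2000)] <- c(50, 500)
  bt@beats$RR[1200] <- 1400
  ev <- eventList("cuff_inflation", "", 600, 630)
  snr <- rep(30, n)
  snr[t >= 1800 & t < 1860] <- -5        # artifact minute
  q <- qualifyBeats(bt, ev, snr_db = snr)
  r <- reasons(q)
  cuffIdx <- which(t >= 585 & t <= 660)
  expect_true(all(vapply(r[cuffIdx], function(x) "cuff" %in% x, logical(1))))
  artIdx <- which(t >= 1800 & t < 1860)
  expect_true(all(vapply(r[artIdx], function(x) "snr" %in% x, logical(1))))
  # the artifact minute loses every beat -> its epoch is disqualified too
  expect_true(all(vapply(r[artIdx], function(x) "epoch" %in% x, logical(1))))
  expect_true("pat_range" %in% r[[500]])
  expect_true("pat_range" %in% r[[2000]])
  expect_true("variability" %in% r[[1200]])
  flagged <- which(!qualified(q))
  # a PAT/RR spike also trips the variability screen on the beat after it
  constructed <- sort(unique(c(cuffIdx, artIdx, 500, 501, 2000, 2001,
                               1200, 1201)))
  expect_setequal(flagged, constructed)
})
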