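test_that("CSV round trip preserves samples and metadata", {
  rec <- multiChannelRecord(
    list(ECG = sin(seq_len(2400) / 10), PPG = cos(seq_len(2400) / 17)),
    fs = 240, units = c(ECG = "mV", PPG = "au"))
  expect_equal(recordDuration(rec), 10)
  p <- withr::local_tempfile(fileext = ".csv")
  writeRecord(rec, p)
  back <- readRecord(p)
  expect_equal(back@channels, rec@channels)
  expect_equal(back@fs, rec@fs)
  expect_equal(back@units, rec@units)
  expect_equal(back@roles, rec@roles)
  expect_equal(back@t0, rec@t0)
})

test_that("CSV supports channels with different sampling rates", {
  rec <- multiChannelRecord(list(ECG = rnorm(1000), PPG = rnorm(500)),
                            fs = c(ECG = 200, PPG = 100))
  p <- withr::local_tempfile(fileext = ".csv")
  writeRecord(rec, p)
  back <- readRecord(p)
  expect_length(channel(back, "PPG"), 500)
  expect_equal(samplingRate(back, "PPG"), 100)
  expect_equal(channel(back, "ECG"), channel(rec, "ECG"))
})

test_that("EDF and WFDB round trips are lossless at 16-bit precision", {
  set.seed(4)
  rec <- multiChannelRecord(
    list(ECG = rnorm(480), ABP = 100 + 20 * sin(seq_len(480) / 40)),
    fs = 240, units = c(ECG = "mV", ABP = "mmHg"), t0 = 3.5)
  for (ext in c(".edf", ".hea")) {
    p <- withr::local_tempfile(fileext = ext)
    writeRecord(rec, p)
    back <- readRecord(p)
    for (ch in c("ECG", "ABP")) {
      # EDF maps min-max onto the 16-bit range; WFDB uses an absolute
      # gain of 32000 adu per max(|x|)
      q <- if (ext == ".edf") diff(range(channel(rec, ch))) / 65535
           else max(abs(channel(rec, ch))) / 32000
      expect_lt(max(abs(channel(back, ch)[1:480] - channel(rec, ch))),
                1.01 * q)
      expect_equal(unname(back@units[ch]), unname(rec@units[ch]))
    }
    expect_equal(back@t0, 3.5)
    expect_equal(samplingRate(back, "ECG"), 240)
    expect_equal(unname(channelRoles(back)[["ABP"]]), "ABP")
  }
})

test_that("record reading rejects missing, empty and rateless inputs", {
  expect_error(readRecord(file.path(tempdir(), "nope.csv")), "no such file")
  p <- withr::local_tempfile(fileext = ".csv")
  file.create(p)
  expect_error(readRecord(p), "empty file")
  writeLines(c("ECG,PPG", "1,2", "3,4"), p)
  expect_error(readRecord(p), "sampling rate missing")
  expect_equal(length(channel(readRecord(p, fs = 240), "ECG")), 2L)
})

test_that("event CSV reading sorts, validates, and keeps overlaps", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("kind,label,start,end",
               "intervention,handgrip,200,290",
               "cuff_inflation,,100,130",
               "intervention,rest,250,370"), p)
  ev <- readEvents(p)
  e <- events(ev)
  expect_equal(e$start, c(100, 200, 250))
  expect_equal(nrow(e), 3L)          # overlap preserved, not merged
  expect_equal(e$kind[1], "cuff_inflation")
  writeLines(c("kind,label,start,end", "activity,walk,50,40"), p)
  expect_error(readEvents(p), "row 1")
  # round trip
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeEvents(ev, p2)
  expect_equal(events(readEvents(p2)), e)
})

test_that("beat table CSV round trip keeps features and reason codes", {
  bt <- regularBeats(dur = 20)
  bt@reasons[[3]] <- c("cuff", "snr")
  bt@qualified[3] <- FALSE
  p <- withr::local_tempfile(fileext = ".csv")
  writeBeatTable(bt, p)
  back <- readBeatTable(p)
  expect_equal(back@beats$PAT, bt@beats$PAT)
  expect_equal(qualified(back), qualified(bt))
  expect_equal(sort(reasons(back)[[3]]), c("cuff", "snr"))
  expect_equal(back@modality, bt@modality)
})

test_that("record validity catches malformed containers", {
  expect_error(multiChannelRecord(list(ECG = numeric()), fs = 100),
               "nonempty")
  expect_error(multiChannelRecord(list(ECG = rnorm(10)), fs = -1),
               "sampling rates")
})
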