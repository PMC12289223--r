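#' RR intervals from R-peak times
#'
#' \code{RR_i = (r_{i+1} - r_i) * 1000} ms, assigned to beat \code{i}; the
#' last beat has no RR.
#'
#' @param r_peaks strictly increasing R-peak times, seconds.
#' @return numeric RR series, ms, of length \code{length(r_peaks) - 1}
#'   (empty when fewer than 2 peaks).
#' @examples
#' computeRR(c(0, 0.8, 1.7))  # 800 900
#' @export
computeRR <- function(r_peaks) {
  if (length(r_peaks) < 2L) return(numeric())
  diff(r_peaks) * 1000
}

#' Pulse arrival time per beat
#'
#' For each R-peak, PAT is the delay to the first pulse upstroke within the
#' pairing window \code{(R, R + min(0.8 * RR, next R - R)]}; R-peaks with
#' no upstroke in the window get NA with reason \code{"unpaired"}. The 80%
#' bound prevents pairing an upstroke with the wrong cardiac cycle.
#'
#' @param r_peaks strictly increasing R-peak times, s.
#' @param upstrokes strictly increasing pulse upstroke times, s.
#' @param window_frac pairing window as a fraction of the current RR.
#' @return list with \code{pat} (ms, NA where unpaired), \code{pulse_beat}
#'   (index into \code{upstrokes}, NA where unpaired) and \code{reason}
#'   (character, \code{""} or \code{"unpaired"}), one entry per R-peak.
#' @export
computePAT <- function(r_peaks, upstrokes, window_frac = 0.8) {
  n <- length(r_peaks)
  pat <- rep(NA_real_, n)
  idx <- rep(NA_integer_, n)
  reason <- rep("", n)
  if (!n) return(list(pat = pat, pulse_beat = idx, reason = reason))
  rr <- if (n >= 2L) diff(r_peaks) else numeric()
  for (i in seq_len(n)) {
    rr_i <- if (i <= length(rr)) rr[i] else if (length(rr)) rr[length(rr)] else Inf
    hi <- r_peaks[i] + window_frac * rr_i
    if (i < n) hi <- min(hi, r_peaks[i + 1L])
    j <- which(upstrokes > r_peaks[i] & upstrokes <= hi)
    if (length(j)) {
      idx[i] <- j[1L]
      pat[i] <- (upstrokes[j[1L]] - r_peaks[i]) * 1000
    } else reason[i] <- "unpaired"
  }
  list(pat = pat, pulse_beat = idx, reason = reason)
}

# first crossing of level within x[from:to]; direction +1 rising, -1 falling.
# Returns fractional sample index (linear interpolation), or NA.
.crossing <- function(x, from, to, level, direction) {
  if (is.na(from) || is.na(to) || to <= from) return(NA_real_)
  seg <- x[from:to]
  if (direction > 0)
    k <- which(seg[-length(seg)] < level & seg[-1] >= level)
  else
    k <- which(seg[-length(seg)] > level & seg[-1] <= level)
  if (!length(k)) return(NA_real_)
  k <- k[1L]
  frac <- (level - seg[k]) / (seg[k + 1L] - seg[k])
  from + (k - 1L) + frac
}

#' Rise/decay time ratio of a pulse beat
#'
#' RDRatio = rise time / decay time, where the rise time runs from 10% to
#' 70% of the foot-to-peak amplitude on the systolic limb and the decay
#' time from 70% down to 10% on the diastolic limb (same amplitude
#' reference). Crossing times are sub-sample, by linear interpolation.
#'
#' @param x filtered pulse waveform (samples).
#' @param fs sampling rate, Hz.
#' @param fiducials data.frame from [detectPulseFiducials()] (needs
#'   \code{foot_i}, \code{peak_i}, \code{beat_end_i}).
#' @return list with \code{rdratio} (one value per fiducial row, NA where a
#'   limb lacks the crossing) and \code{reason} (\code{""} or
#'   \code{"no_crossing"}).
#' @export
computeRDRatio <- function(x, fs, fiducials) {
  m <- nrow(fiducials)
  rd <- rep(NA_real_, m)
  reason <- rep("", m)
  for (k in seq_len(m)) {
    fi <- fiducials$foot_i[k]; pi <- fiducials$peak_i[k]
    ei <- fiducials$beat_end_i[k]
    if (anyNA(c(fi, pi, ei))) { reason[k] <- "no_crossing"; next }
    amp <- x[pi] - x[fi]
    if (!is.finite(amp) || amp <= 0) { reason[k] <- "no_crossing"; next }
    lo <- x[fi] + 0.1 * amp
    hi <- x[fi] + 0.7 * amp
    r10 <- .crossing(x, fi, pi, lo, +1)
    r70 <- .crossing(x, fi, pi, hi, +1)
    d70 <- .crossing(x, pi, ei, hi, -1)
    d10 <- if (!is.na(d70)) .crossing(x, ceiling(d70), ei, lo, -1) else NA
    if (anyNA(c(r10, r70, d70, d10)) || d10 <= d70 || r70 <= r10) {
      reason[k] <- "no_crossing"; next
    }
    rd[k] <- (r70 - r10) / (d10 - d70)
  }
  list(rdratio = rd, reason = reason)
}

#' Amplitude features of pulse beats
#'
#' PeakAmp is the foot-referenced pulse amplitude (AC amplitude) for PPG,
#' and the absolute systolic value for pressure channels, where it equals
#' SBP in mmHg. Upstroke is the maximum of the first derivative within the
#' beat (the slope at the upstroke fiducial), in units/s.
#'
#' @param x filtered pulse waveform.
#' @param fiducials data.frame from [detectPulseFiducials()].
#' @param pressure TRUE for pressure channels (ABP, VCP): PeakAmp is then
#'   the absolute peak value (= SBP).
#' @return data.frame with \code{PeakAmp}, \code{Upstroke} and (pressure
#'   channels) \code{SBP}, one row per beat; NA where the peak is absent.
#' @export
computeAmplitudeFeatures <- function(x, fiducials, pressure = FALSE) {
  pk <- fiducials$peak_i
  ft <- fiducials$foot_i
  peakVal <- ifelse(is.na(pk), NA_real_, x[pk])
  footVal <- ifelse(is.na(ft), NA_real_, x[ft])
  out <- data.frame(
    PeakAmp = if (pressure) peakVal else peakVal - footVal,
    Upstroke = fiducials$upstroke_slope)
  out$Upstroke[is.na(pk)] <- NA_real_
  if (pressure) out$SBP <- peakVal
  out
}

#' Build a per-beat feature table from a recording
#'
#' Runs the full beat-level chain for one pulse channel: ECG R-peak
#' detection, pulse preprocessing and fiducial detection, then RR, PAT,
#' PeakAmp, Upstroke, RDRatio and (pressure channels) SBP per beat, anchored
#' at R-peak times. Beats whose pulse counterpart is missing or lacks a
#' feature crossing carry reason codes and start out disqualified; the
#' remaining quality criteria are applied by [qualifyBeats()].
#'
#' @param record a [MultiChannelRecord-class] with an ECG channel and the
#'   requested pulse channel.
#' @param pulse pulse channel name or role (default the record's first
#'   non-ECG role among PPG, ABP, VCP).
#' @param ... passed to [detectPulseFiducials()].
#' @return a [BeatTable-class].
#' @export
beatTable <- function(record, pulse = NULL, ...) {
  stopifnot(is(record, "MultiChannelRecord"))
  ecgName <- .resolveChannel(record, "ECG")
  if (is.null(pulse)) {
    cand <- names(record@roles)[record@roles %in% c("PPG", "ABP", "VCP")]
    if (!length(cand)) stop("record has no pulse channel", call. = FALSE)
    pulse <- cand[[1L]]
  }
  pulseName <- .resolveChannel(record, pulse)
  modality <- unname(record@roles[[pulseName]])
  pressure <- modality %in% c("ABP", "VCP")

  rp <- detectRPeaks(channel(record, ecgName), samplingRate(record, ecgName),
                     t0 = record@t0)
  px <- channel(record, pulseName)
  pfs <- samplingRate(record, pulseName)
  fid <- detectPulseFiducials(px, pfs, t0 = record@t0, ...)
  filt <- preprocessSignal(px, pfs)$filtered

  n <- length(rp)
  rr <- c(computeRR(rp), NA_real_)
  pairing <- computePAT(rp, fid$upstroke_t)
  rdAll <- computeRDRatio(filt, pfs, fid)
  ampAll <- computeAmplitudeFeatures(filt, fid, pressure = pressure)

  pick <- function(v) ifelse(is.na(pairing$pulse_beat), NA_real_,
                             v[pairing$pulse_beat])
  beats <- data.frame(
    t = rp, RR = rr, PAT = pairing$pat,
    PeakAmp = pick(ampAll$PeakAmp), Upstroke = pick(ampAll$Upstroke),
    RDRatio = pick(rdAll$rdratio))
  if (pressure) beats$SBP <- pick(ampAll$SBP)

  reasons <- lapply(seq_len(n), function(i) {
    r <- character()
    if (pairing$reason[i] == "unpaired") r <- c(r, "unpaired")
    else if (!is.na(pairing$pulse_beat[i]) &&
             rdAll$reason[pairing$pulse_beat[i]] == "no_crossing")
      r <- c(r, "no_crossing")
    r
  })
  new("BeatTable", beats = beats, modality = modality,
      qualified = lengths(reasons) == 0L, reasons = reasons)
}

#' Assemble a beat table from per-beat series
#'
#' Constructor used when beat features come from elsewhere than waveform
#' extraction (e.g. directly from the simulator's beat-level output).
#'
#' @param t R-peak times, s (strictly increasing).
#' @param RR,PAT,PeakAmp,Upstroke,RDRatio,SBP optional per-beat series (ms,
#'   ms, units, units/s, unitless, mmHg); RR defaults to \code{diff(t)}.
#' @param modality pulse modality label.
#' @return a [BeatTable-class] with all beats initially qualified.
#' @export
asBeatTable <- function(t, RR = NULL, PAT = NULL, PeakAmp = NULL,
                        Upstroke = NULL, RDRatio = NULL, SBP = NULL,
                        modality = "PPG") {
  n <- length(t)
  if (is.null(RR)) RR <- c(diff(t) * 1000, NA_real_)
  beats <- data.frame(t = t, RR = RR)
  for (col in c("PAT", "PeakAmp", "Upstroke", "RDRatio", "SBP")) {
    v <- get(col)
    if (!is.null(v)) {
      stopifnot(length(v) == n)
      beats[[col]] <- v
    }
  }
  new("BeatTable", beats = beats, modality = modality,
      qualified = rep(TRUE, n), reasons = rep(list(character()), n))
}
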