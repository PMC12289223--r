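#' Low-pass filter and differentiate a waveform
#'
#' Zero-phase Butterworth low-pass (default 10 Hz cutoff, order 4,
#' forward-backward) followed by a central-difference differentiator scaled
#' to signal units per second. All pulse fiducial points are located on the
#' derivative of this filtered signal.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate, Hz; must exceed 20 Hz so the cutoff sits below
#'   Nyquist.
#' @param cutoff low-pass cutoff, Hz.
#' @param order Butterworth order.
#' @return list with \code{filtered} and \code{derivative}, both the length
#'   of \code{x}.
#' @examples
#' p <- preprocessSignal(sin(2 * pi * 1 * seq(0, 2, by = 1/100)), fs = 100)
#' range(p$derivative)
#' @export
preprocessSignal <- function(x, fs, cutoff = 10, order = 4) {
  if (fs <= 20)
    stop("sampling rate must exceed 20 Hz (cutoff ", cutoff,
         " Hz needs headroom below Nyquist)", call. = FALSE)
  stopifnot(is.numeric(x), length(x) > 3 * order)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # filter around the mean to keep forward-backward edge transients small
  mu <- mean(x)
  filtered <- as.numeric(signal::filtfilt(bf, x - mu)) + mu
  n <- length(filtered)
  derivative <- numeric(n)
  derivative[2:(n - 1)] <- (filtered[3:n] - filtered[1:(n - 2)]) * fs / 2
  derivative[1] <- (filtered[2] - filtered[1]) * fs
  derivative[n] <- (filtered[n] - filtered[n - 1]) * fs
  list(filtered = filtered, derivative = derivative)
}

# sub-sample refinement of a local extremum at index i by fitting a
# parabola through (i-1, i, i+1); returns the fractional offset in samples
.parabolicOffset <- function(v, i) {
  if (i <= 1L || i >= length(v)) return(0)
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  if (denom == 0) return(0)
  off <- 0.5 * (v[i - 1L] - v[i + 1L]) / denom
  if (abs(off) > 1) 0 else off
}

# local maxima indices of v (strict on the right to break flat ties left)
.localMaxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
}

# block-adaptive amplitude threshold: for each sample, frac * max of its
# block (blocks of block_s seconds), with a global noise floor
.blockThreshold <- function(v, fs, frac, block_s = 10) {
  n <- length(v)
  bl <- pmax(1L, as.integer(round(block_s * fs)))
  blk <- (seq_len(n) - 1L) %/% bl
  bmax <- tapply(v, blk, max)
  floor_ <- 1e-3 * max(v, 0)
  pmax(frac * as.numeric(bmax)[blk + 1L], floor_, 1e-12)
}

#' Detect ECG R-peaks
#'
#' Derivative-energy detector with block-adaptive amplitude thresholding
#' and a 200 ms refractory period: the squared derivative of the filtered
#' ECG is integrated over a 150 ms window, local maxima above the adaptive
#' threshold mark candidate beats, and each candidate is refined to the
#' ECG maximum within +/- 100 ms.
#'
#' @param ecg numeric ECG samples.
#' @param fs sampling rate, Hz.
#' @param refractory_s minimum inter-peak interval, seconds.
#' @param t0 time of the first sample, seconds.
#' @return strictly increasing numeric vector of R-peak times (s). A signal
#'   with no detectable peaks returns an empty vector with a warning.
#' @export
detectRPeaks <- function(ecg, fs, refractory_s = 0.2, t0 = 0) {
  if (length(ecg) < 2 * fs)
    stop("need at least 2 s of ECG", call. = FALSE)
  pp <- preprocessSignal(ecg, fs, cutoff = min(15, fs / 2.5))
  e <- pp$derivative^2
  w <- max(1L, as.integer(round(0.15 * fs)))
  e <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  e[is.na(e)] <- 0
  if (max(e) <= 0 || stats::sd(ecg) == 0) {
    warning("no R-peaks found (flat signal)")
    return(numeric())
  }
  thr <- .blockThreshold(e, fs, frac = 0.2)
  cand <- .localMaxima(e)
  cand <- cand[e[cand] > thr[cand]]
  if (!length(cand)) {
    warning("no R-peaks found")
    return(numeric())
  }
  # refine to the ECG extremum near each energy peak
  half <- as.integer(round(0.1 * fs))
  ref <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(length(ecg), i + half)
    seg <- pp$filtered[lo:hi]
    lo + which.max(abs(seg - stats::median(seg))) - 1L
  }, integer(1))
  ref <- sort(unique(ref))
  # refractory: greedy, keep the larger peak of any pair closer than 200 ms
  amp <- abs(pp$filtered[ref])
  keep <- integer()
  for (i in ref) {
    if (length(keep) && (i - keep[length(keep)]) < refractory_s * fs) {
      if (abs(pp$filtered[i]) > abs(pp$filtered[keep[length(keep)]]))
        keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  # sub-sample timing via a parabolic fit around each refined extremum
  absf <- abs(pp$filtered - stats::median(pp$filtered))
  t0 + (keep - 1L + vapply(keep, function(i) .parabolicOffset(absf, i),
                           numeric(1))) / fs
}

#' Detect pulse-wave fiducial points
#'
#' Locates, per beat, the upstroke (maximum of the first derivative), foot,
#' systolic peak, shoulder, dicrotic notch and secondary peak of a pulse
#' waveform (PPG, arterial line or volume-clamp). The upstroke is found
#' first as a prominent derivative maximum; the foot is the last preceding
#' sample where the derivative falls below \code{foot_frac} of the beat's
#' derivative maximum; peak, notch and secondary peak follow from
#' sign changes of the derivative after the upstroke. Points a beat's
#' morphology lacks are returned as NA, never fabricated.
#'
#' Beats span foot to foot; leading and trailing partial beats are dropped.
#'
#' @param pulse numeric pulse samples.
#' @param fs sampling rate, Hz.
#' @param foot_frac fraction of the per-beat derivative maximum used in the
#'   backward foot search.
#' @param refractory_s minimum upstroke spacing, seconds.
#' @param t0 time of the first sample, seconds.
#' @return data.frame (one row per beat): \code{foot_t}, \code{upstroke_t},
#'   \code{peak_t}, \code{shoulder_t}, \code{notch_t},
#'   \code{secondary_peak_t}, \code{beat_end_t} (next foot),
#'   \code{upstroke_slope} (units/s), plus the matching sample indices
#'   (\code{foot_i}, \code{peak_i}, \code{beat_end_i}).
#' @export
detectPulseFiducials <- function(pulse, fs, foot_frac = 0.2,
                                 refractory_s = 0.3, t0 = 0) {
  pp <- preprocessSignal(pulse, fs)
  f <- pp$filtered; d <- pp$derivative
  n <- length(f)
  dpos <- pmax(d, 0)
  if (max(dpos) <= 0) return(.emptyFiducials())
  thr <- .blockThreshold(dpos, fs, frac = 0.3)
  ups <- .localMaxima(d)
  ups <- ups[d[ups] > thr[ups]]
  if (!length(ups)) return(.emptyFiducials())
  keep <- integer()
  for (i in ups) {
    if (length(keep) && (i - keep[length(keep)]) < refractory_s * fs) {
      if (d[i] > d[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  ups <- keep
  m <- length(ups)
  feet <- integer(m)
  for (k in seq_len(m)) {
    u <- ups[k]
    lo <- if (k > 1L) ups[k - 1L] else max(1L, u - as.integer(2 * fs))
    j <- u
    cut <- foot_frac * d[u]
    while (j > lo && d[j] > cut) j <- j - 1L
    feet[k] <- j
  }
  rows <- vector("list", m)
  for (k in seq_len(m)) {
    u <- ups[k]
    endi <- if (k < m) feet[k + 1L] else NA_integer_
    if (is.na(endi)) next                      # trailing partial beat
    if (k == 1L && feet[k] <= 1L) next         # leading partial beat
    seg <- feet[k]:endi
    # systolic peak: first + to - derivative crossing after the upstroke
    dd <- d[u:endi]
    zc <- which(dd[-length(dd)] > 0 & dd[-1] <= 0)
    peaki <- if (length(zc)) u + zc[1] - 1L else NA_integer_
    notchi <- shoulderi <- sec_i <- NA_integer_
    if (!is.na(peaki) && peaki < endi) {
      da <- d[peaki:endi]
      up_cross <- which(da[-length(da)] < 0 & da[-1] >= 0)   # - to +
      if (length(up_cross)) {
        notchi <- peaki + up_cross[1] - 1L
        db <- d[notchi:endi]
        down_cross <- which(db[-length(db)] > 0 & db[-1] <= 0)
        if (length(down_cross)) sec_i <- notchi + down_cross[1] - 1L
      }
      # shoulder: decay deceleration — local max of the (negative)
      # derivative between peak and notch that stays below zero
      hi <- if (!is.na(notchi)) notchi else endi
      if (hi - peaki > 2L) {
        lm <- .localMaxima(d[peaki:hi])
        lm <- lm[d[peaki + lm - 1L] < 0]
        if (length(lm)) shoulderi <- peaki + lm[1] - 1L
      }
    }
    rows[[k]] <- data.frame(
      foot_i = feet[k], upstroke_i = u, peak_i = peaki,
      shoulder_i = shoulderi, notch_i = notchi, secondary_peak_i = sec_i,
      beat_end_i = endi, upstroke_slope = d[u])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) return(.emptyFiducials())
  ti <- function(i) t0 + (i - 1L) / fs
  # upstroke with sub-sample refinement on the derivative peak
  out$foot_t <- ti(out$foot_i)
  out$upstroke_t <- ti(out$upstroke_i) +
    vapply(out$upstroke_i, function(i) .parabolicOffset(d, i),
           numeric(1)) / fs
  out$peak_t <- ti(out$peak_i); out$shoulder_t <- ti(out$shoulder_i)
  out$notch_t <- ti(out$notch_i)
  out$secondary_peak_t <- ti(out$secondary_peak_i)
  out$beat_end_t <- ti(out$beat_end_i)
  rownames(out) <- NULL
  out
}

.emptyFiducials <- function() {
  data.frame(foot_i = integer(), upstroke_i = integer(), peak_i = integer(),
             shoulder_i = integer(), notch_i = integer(),
             secondary_peak_i = integer(), beat_end_i = integer(),
             upstroke_slope = numeric(), foot_t = numeric(),
             upstroke_t = numeric(), peak_t = numeric(),
             shoulder_t = numeric(), notch_t = numeric(),
             secondary_peak_t = numeric(), beat_end_t = numeric())
}
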