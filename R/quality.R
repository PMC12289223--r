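#' Cuff-inflation blanking
#'
#' Flags every beat falling within \code{[start - cuff_pre_s, start +
#' cuff_post_s]} of a cuff inflation start (defaults 15 s before, 60 s
#' after), since the occlusion corrupts the distal pulse. Overlapping
#' blanking windows are applied as their union.
#'
#' @param t beat times, s.
#' @param ev an [EventList-class]; only \code{cuff_inflation} events are
#'   used.
#' @param cfg a [qualityConfig()].
#' @return logical per beat: TRUE = flagged (\code{"cuff"}).
#' @export
blankCuff <- function(t, ev, cfg = qualityConfig()) {
  flagged <- rep(FALSE, length(t))
  if (is.null(ev)) return(flagged)
  cuffs <- ev@events[ev@events$kind == "cuff_inflation", , drop = FALSE]
  for (s in cuffs$start)
    flagged <- flagged | (t >= s - cfg$cuff_pre_s & t <= s + cfg$cuff_post_s)
  flagged
}

#' Template-based morphology SNR
#'
#' For each pulse beat, the beat waveform (foot to foot, time-normalized to
#' \code{npoints} samples and mean-centered) is compared to a reference
#' template formed as the pointwise median of 5 consecutive beats around
#' it. Noise is the deviation of the beat from this template; SNR is the
#' template-to-residual power ratio in dB. Beats below
#' \code{cfg$snr_threshold_db} are flagged.
#'
#' @param pulse filtered pulse waveform.
#' @param fs sampling rate, Hz.
#' @param fiducials data.frame from [detectPulseFiducials()].
#' @param cfg a [qualityConfig()].
#' @param npoints samples per time-normalized beat.
#' @return list with \code{snr_db} (per beat; Inf for an exact template
#'   match) and \code{flagged} (logical). With fewer than
#'   \code{cfg$template_beats} beats, all are flagged with a warning.
#' @export
templateSNR <- function(pulse, fs, fiducials, cfg = qualityConfig(),
                        npoints = 100L) {
  m <- nrow(fiducials)
  k <- cfg$template_beats
  if (m < k) {
    warning("fewer than ", k, " beats: all flagged by SNR criterion")
    return(list(snr_db = rep(-Inf, m), flagged = rep(TRUE, m)))
  }
  mat <- matrix(NA_real_, m, npoints)
  for (i in seq_len(m)) {
    seg <- pulse[fiducials$foot_i[i]:fiducials$beat_end_i[i]]
    y <- stats::approx(seq_along(seg), seg, n = npoints)$y
    mat[i, ] <- y - mean(y)
  }
  half <- (k - 1L) %/% 2L
  snr <- numeric(m)
  for (i in seq_len(m)) {
    lo <- max(1L, min(i - half, m - k + 1L))
    tmpl <- apply(mat[lo:(lo + k - 1L), , drop = FALSE], 2L, stats::median)
    resid <- mat[i, ] - tmpl
    ps <- sum(tmpl^2); pn <- sum(resid^2)
    snr[i] <- if (pn == 0) Inf else 10 * log10(ps / pn)
  }
  list(snr_db = snr, flagged = snr < cfg$snr_threshold_db)
}

#' Physiologic PAT range filter
#'
#' Valid PAT assumes a fixed pulse path length and pulse-wave velocity
#' between \code{pwv_min} and \code{pwv_max}; see [patBounds()]. PAT
#' outside the range (or NA) is flagged.
#'
#' @param pat PAT series, ms.
#' @param cfg a [qualityConfig()].
#' @return logical per beat: TRUE = flagged (\code{"pat_range"}).
#' @examples
#' patRangeFilter(c(150, 40, 450))  # FALSE TRUE TRUE at the 0.8 m default
#' @export
patRangeFilter <- function(pat, cfg = qualityConfig()) {
  b <- patBounds(cfg)
  !is.na(pat) & (pat < b[1] | pat > b[2])
}

#' Beat-to-beat variability filter
#'
#' Flags drastic beat-to-beat changes: beat \code{i} is flagged when
#' \code{|RR_i - RR_{i-1}| / RR_{i-1}} exceeds \code{max_rel_delta_rr}, or
#' analogously for PAT. The first beat is never flagged (no predecessor);
#' comparisons involving NA do not flag.
#'
#' @param rr RR series, ms.
#' @param pat PAT series, ms (optional).
#' @param cfg a [qualityConfig()].
#' @return logical per beat: TRUE = flagged (\code{"variability"}).
#' @export
variabilityFilter <- function(rr, pat = NULL, cfg = qualityConfig()) {
  jump <- function(x, thr) {
    n <- length(x)
    f <- rep(FALSE, n)
    if (n >= 2L) {
      rel <- abs(x[-1] - x[-n]) / x[-n]
      f[-1] <- !is.na(rel) & rel > thr
    }
    f
  }
  f <- jump(rr, cfg$max_rel_delta_rr)
  if (!is.null(pat)) f <- f | jump(pat, cfg$max_rel_delta_pat)
  f
}

#' Epoch-level persistence qualification
#'
#' Partitions the record into \code{epoch_s} epochs (60 s default) aligned
#' to multiples of \code{epoch_s}. The ECG defines the expected number of
#' cardiac cycles per epoch; if fewer than \code{min_beat_fraction} (at
#' least 50%, inclusive) of them have a present, still-qualified pulse
#' beat, every beat of the epoch is flagged. Applied after the other four
#' criteria by contract.
#'
#' @param t beat (R-peak) times, s.
#' @param pulse_ok logical per beat: pulse beat present and not flagged by
#'   criteria 1-4.
#' @param cfg a [qualityConfig()].
#' @return logical per beat: TRUE = flagged (\code{"epoch"}).
#' @export
epochQualify <- function(t, pulse_ok, cfg = qualityConfig()) {
  stopifnot(length(t) == length(pulse_ok))
  flagged <- rep(FALSE, length(t))
  if (!length(t)) return(flagged)
  ep <- floor(t / cfg$epoch_s)
  for (e in unique(ep)) {
    sel <- ep == e
    n_ecg <- sum(sel)
    if (n_ecg == 0L) next
    if (sum(pulse_ok[sel]) / n_ecg < cfg$min_beat_fraction)
      flagged[sel] <- TRUE
  }
  # interior epochs with no ECG beats at all are suspect in themselves
  allep <- seq(min(ep), max(ep))
  if (length(setdiff(allep, unique(ep))))
    warning("epoch(s) with zero ECG beats: ",
            paste(setdiff(allep, unique(ep)), collapse = ", "))
  flagged
}

#' Apply the ambulatory qualification criteria to a beat table
#'
#' Merges the five criteria into the table's quality mask, in order: cuff
#' blanking, template SNR (when \code{snr_db} is supplied), PAT range,
#' beat-to-beat variability, and finally the 1-minute epoch persistence
#' rule. Criteria only remove beats, never reinstate them, and reapplying
#' the same criteria is idempotent.
#'
#' @param bt a [BeatTable-class].
#' @param ev an [EventList-class] or NULL.
#' @param cfg a [qualityConfig()].
#' @param snr_db optional per-beat SNR (dB) aligned with the table (e.g.
#'   [templateSNR()] output mapped through the beat pairing).
#' @return the [BeatTable-class] with updated \code{qualified}/reason
#'   codes.
#' @export
qualifyBeats <- function(bt, ev = NULL, cfg = qualityConfig(),
                         snr_db = NULL) {
  stopifnot(is(bt, "BeatTable"))
  b <- bt@beats
  reasons <- bt@reasons
  add <- function(reasons, flagged, code) {
    for (i in which(flagged))
      reasons[[i]] <- union(reasons[[i]], code)
    reasons
  }
  reasons <- add(reasons, blankCuff(b$t, ev, cfg), "cuff")
  if (!is.null(snr_db)) {
    stopifnot(length(snr_db) == nrow(b))
    reasons <- add(reasons, !is.na(snr_db) & snr_db < cfg$snr_threshold_db,
                   "snr")
  }
  if (!is.null(b$PAT))
    reasons <- add(reasons, patRangeFilter(b$PAT, cfg), "pat_range")
  reasons <- add(reasons, variabilityFilter(b$RR, b$PAT, cfg), "variability")
  pulse_ok <- lengths(reasons) == 0L &
    if (!is.null(b$PAT)) !is.na(b$PAT) else TRUE
  reasons <- add(reasons, epochQualify(b$t, pulse_ok, cfg), "epoch")
  new("BeatTable", beats = b, modality = bt@modality,
      qualified = lengths(reasons) == 0L, reasons = reasons)
}
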