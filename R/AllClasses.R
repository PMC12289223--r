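#' @import methods
NULL

#' Multichannel physiological recording
#'
#' Container for synchronized raw waveforms (ECG plus one or more pulse
#' channels) sharing a common time origin. Channels may have different
#' sampling rates; sample \code{i} of channel \code{c} occurs at
#' \code{t0 + i / fs[c]} seconds (0-based \code{i}).
#'
#' @slot channels named list of numeric sample vectors.
#' @slot fs named numeric, per-channel sampling rate in Hz.
#' @slot units named character, per-channel unit string (mV, au, mmHg).
#' @slot roles named character, channel role: one of \code{"ECG"},
#'   \code{"PPG"}, \code{"ABP"}, \code{"VCP"}, \code{"other"}.
#' @slot t0 numeric(1), record start time in seconds.
#'
#' @seealso [readRecord()], [writeRecord()], [channel()], [samplingRate()]
#' @export
setClass("MultiChannelRecord",
  slots = c(
    channels = "list",
    fs = "numeric",
    units = "character",
    roles = "character",
    t0 = "numeric"
  )
)

setValidity("MultiChannelRecord", function(object) {
  msg <- character()
  nm <- names(object@channels)
  if (length(object@channels) == 0L) msg <- c(msg, "record has no channels")
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm))
    msg <- c(msg, "channels must have unique non-empty names")
  if (!all(vapply(object@channels, is.numeric, logical(1))))
    msg <- c(msg, "all channels must be numeric vectors")
  if (any(vapply(object@channels, length, integer(1)) == 0L))
    msg <- c(msg, "all channel arrays must be nonempty")
  for (s in c("fs", "units", "roles")) {
    v <- slot(object, s)
    if (!identical(sort(names(v)), sort(nm %||% character())))
      msg <- c(msg, sprintf("'%s' must be named to match channels", s))
  }
  if (any(!is.finite(object@fs)) || any(object@fs <= 0))
    msg <- c(msg, "sampling rates must be finite and > 0")
  bad <- setdiff(object@roles, c("ECG", "PPG", "ABP", "VCP", "other"))
  if (length(bad))
    msg <- c(msg, paste("unknown channel role(s):", paste(bad, collapse = ", ")))
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Event annotations
#'
#' Timed annotations attached to a recording: cuff inflations, labeled
#' intervention intervals (rest, paced breathing, handgrip) and activities.
#' Events are kept sorted by start time; overlaps are allowed and preserved.
#'
#' @slot events data.frame with columns \code{kind} (one of
#'   \code{cuff_inflation}, \code{intervention}, \code{activity}),
#'   \code{label}, \code{start}, \code{end} (seconds from record start).
#'
#' @seealso [readEvents()], [blankCuff()]
#' @export
setClass("EventList", slots = c(events = "data.frame"))

setValidity("EventList", function(object) {
  ev <- object@events
  req <- c("kind", "label", "start", "end")
  if (!all(req %in% names(ev)))
    return(paste("events need columns", paste(req, collapse = ", ")))
  msg <- character()
  if (nrow(ev)) {
    if (!all(ev$kind %in% c("cuff_inflation", "intervention", "activity")))
      msg <- c(msg, "unknown event kind")
    if (any(ev$end < ev$start))
      msg <- c(msg, "event end < start")
    if (is.unsorted(ev$start))
      msg <- c(msg, "events must be sorted by start time")
  }
  if (length(msg)) msg else TRUE
})

#' Per-beat feature table
#'
#' One row per detected cardiac cycle, anchored at the ECG R-peak time, with
#' the beat features used for BRS estimation and the quality mask attached by
#' the qualification criteria.
#'
#' @slot beats data.frame with columns \code{t} (R-peak time, s; strictly
#'   increasing), \code{RR} (ms), and, per pulse channel, \code{PAT} (ms),
#'   \code{PeakAmp} (signal units; equals SBP in mmHg for pressure channels),
#'   \code{Upstroke} (signal units/s), \code{RDRatio} (dimensionless),
#'   \code{SBP} (mmHg, pressure channels only). Missing features are NA.
#' @slot modality character(1), pulse modality the features belong to
#'   (\code{"PPG"}, \code{"ABP"}, \code{"VCP"}, or \code{""} if ECG only).
#' @slot qualified logical per beat; TRUE iff no disqualification reason.
#' @slot reasons list of character vectors per beat, each a subset of
#'   \code{c("cuff","snr","pat_range","variability","epoch","unpaired",
#'   "no_crossing")}.
#'
#' @seealso [beatTable()], [qualifyBeats()], [writeBeatTable()]
#' @export
setClass("BeatTable",
  slots = c(
    beats = "data.frame",
    modality = "character",
    qualified = "logical",
    reasons = "list"
  )
)

setValidity("BeatTable", function(object) {
  b <- object@beats
  msg <- character()
  if (!all(c("t", "RR") %in% names(b)))
    msg <- c(msg, "beats need at least columns t and RR")
  n <- nrow(b)
  if (n > 1L && any(diff(b$t) <= 0))
    msg <- c(msg, "beat times must be strictly increasing")
  if ("RR" %in% names(b) && any(b$RR <= 0, na.rm = TRUE))
    msg <- c(msg, "RR must be > 0 where defined")
  if ("PAT" %in% names(b) && any(b$PAT <= 0, na.rm = TRUE))
    msg <- c(msg, "PAT must be > 0 where defined")
  if ("RDRatio" %in% names(b) && any(b$RDRatio <= 0, na.rm = TRUE))
    msg <- c(msg, "RDRatio must be > 0 where defined")
  if (length(object@qualified) != n || length(object@reasons) != n)
    msg <- c(msg, "qualified/reasons must have one entry per beat")
  if (n && !identical(object@qualified,
                      lengths(object@reasons) == 0L))
    msg <- c(msg, "qualified must be TRUE exactly when reasons is empty")
  if (length(msg)) msg else TRUE
})

#' Cross-spectral transfer-function estimate
#'
#' Welch-averaged auto- and cross-spectra between an input beat-feature
#' series (SBP or a surrogate) and the RR-interval series, with the complex
#' transfer function H = Pxy / Pxx and magnitude-squared coherence.
#'
#' @slot f one-sided frequency grid, Hz.
#' @slot Pxx,Pyy auto-spectral densities of input and output.
#' @slot Pxy complex cross-spectral density.
#' @slot H complex transfer function, \code{Pxy / Pxx}.
#' @slot msc magnitude-squared coherence in [0, 1] at every bin.
#' @slot nSegments number of Welch segments averaged.
#' @slot fs sampling rate of the uniform series, Hz.
#' @slot config the [spectralConfig()] used.
#'
#' @seealso [estimateTransfer()], [gain()], [coherence()], [brsIndex()]
#' @export
setClass("TransferEstimate",
  slots = c(
    f = "numeric", Pxx = "numeric", Pyy = "numeric",
    Pxy = "complex", H = "complex", msc = "numeric",
    nSegments = "integer", fs = "numeric", config = "list"
  )
)

setValidity("TransferEstimate", function(object) {
  n <- length(object@f)
  msg <- character()
  if (!all(lengths(list(object@Pxx, object@Pyy, object@Pxy,
                        object@H, object@msc)) == n))
    msg <- c(msg, "spectral slots must share the frequency grid length")
  if (any(object@msc < 0 | object@msc > 1, na.rm = TRUE))
    msg <- c(msg, "msc must lie in [0, 1]")
  if (any(object@Pxx < 0) || any(object@Pyy < 0))
    msg <- c(msg, "auto-spectra must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Band-averaged baroreflex sensitivity index
#'
#' The BRS index for one analysis window: transfer gain averaged over the
#' low-frequency band (0.04-0.15 Hz), the mean LF coherence, and whether the
#' window passes the coherence qualification threshold.
#'
#' @slot value band-averaged gain; ms/mmHg when the input is SBP, ms/ms for
#'   PAT, ms per unit for RDRatio, arbitrary units otherwise.
#' @slot meanLFCoherence mean magnitude-squared coherence over the LF bins.
#' @slot qualified TRUE iff \code{meanLFCoherence >=} the configured
#'   coherence threshold (default 0.14).
#' @slot window numeric(2), analysis window (start, end) in seconds.
#' @slot inputFeature name of the input feature (e.g. \code{"SBP"},
#'   \code{"PAT"}, \code{"RDRatio"}).
#' @slot modality pulse modality the input came from.
#'
#' @seealso [brsIndex()]
#' @export
setClass("BRSIndex",
  slots = c(
    value = "numeric", meanLFCoherence = "numeric", qualified = "logical",
    window = "numeric", inputFeature = "character", modality = "character"
  )
)

setValidity("BRSIndex", function(object) {
  msg <- character()
  if (length(object@value) != 1L || (is.finite(object@value) && object@value < 0))
    msg <- c(msg, "value must be a single nonnegative number")
  if (length(object@window) != 2L)
    msg <- c(msg, "window must be (start, end)")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated hemodynamics run
#'
#' Beat-level output of the open-loop baroreflex simulator: the observed
#' (noisy) per-beat series the analysis sees, the pre-noise series that
#' satisfy the configured couplings exactly, the true reflex gain per beat,
#' and the scheduled events.
#'
#' @slot t beat (R-peak) times, seconds.
#' @slot sbp,rr,pat,rdr observed per-beat series (with noise): SBP (mmHg),
#'   RR (ms), PAT (ms), rise/decay ratio.
#' @slot trueSbp,trueRr,truePat,trueRdr pre-noise series obeying the
#'   configured linear couplings exactly.
#' @slot trueGain true baroreflex gain per beat, ms/mmHg.
#' @slot events scheduled [EventList-class] (cuff inflations, activities).
#' @slot config the [simConfig()] used.
#'
#' @seealso [simulateBeats()], [renderSignals()], [scenario24h()]
#' @export
setClass("SimGroundTruth",
  slots = c(
    t = "numeric",
    sbp = "numeric", rr = "numeric", pat = "numeric", rdr = "numeric",
    trueSbp = "numeric", trueRr = "numeric", truePat = "numeric",
    trueRdr = "numeric", trueGain = "numeric",
    events = "EventList", config = "list"
  )
)

setValidity("SimGroundTruth", function(object) {
  n <- length(object@t)
  same <- all(lengths(list(object@sbp, object@rr, object@pat, object@rdr,
                           object@trueSbp, object@trueRr, object@truePat,
                           object@trueRdr, object@trueGain)) == n)
  if (!same) return("all per-beat slots must have one value per beat")
  if (n > 1L && any(diff(object@t) <= 0))
    return("beat times must be strictly increasing")
  TRUE
})

#' Interventional study result
#'
#' Aggregated output of [runInterventional()]: the per-participant,
#' per-intervention BRS indices (median over repeated sessions), the
#' intra-participant precision and inter-participant variation of every
#' index, and the cross-index correlation tables.
#'
#' @slot brs data.frame (participant, intervention, index, value) where
#'   \code{value} is the median BRS over the available repeats.
#' @slot precision data.frame (index, intra_pct, inter_pct).
#' @slot correlations list with matrices \code{pearson}, \code{spearman},
#'   \code{p_pearson}, \code{p_spearman} across indices.
#'
#' @seealso [runInterventional()], [intraPrecision()], [interVariation()]
#' @export
setClass("StudyResult",
  slots = c(brs = "data.frame", precision = "data.frame",
            correlations = "list")
)

#' Ambulatory 24-hour BRS profile
#'
#' Output of [runAmbulatory()] on a 15-minute time grid: median BRS of
#' coherence-qualified 4-minute windows within each 1-hour span, with
#' standard errors, median coherence, the qualified-window percentage, HRV
#' band powers, heart rate and any cuff SBP readings.
#'
#' @slot grid data.frame with one row per 15-minute grid point. Columns:
#'   \code{t} (grid time, s), per input feature \code{BRS_<f>},
#'   \code{se_<f>}, \code{coh_<f>}, \code{qualified_pct_<f>}, plus
#'   \code{HRV_LF}, \code{HRV_HF} (ms^2), \code{HR} (bpm), \code{cuffSBP}
#'   (mmHg, NA when no reading fell in the span).
#' @slot windows data.frame of all 4-minute window estimates (t_start,
#'   t_end, feature, value, coherence, qualified, reason) for audit.
#'
#' @seealso [runAmbulatory()]
#' @export
setClass("AmbulatoryProfile",
  slots = c(grid = "data.frame", windows = "data.frame")
)

setValidity("AmbulatoryProfile", function(object) {
  g <- object@grid
  if (nrow(g) > 1L && any(abs(diff(g$t) - 900) > 1e-9))
    return("grid spacing must be 900 s")
  qp <- unlist(g[grep("^qualified_pct_", names(g))])
  if (length(qp) && any(qp < 0 | qp > 100, na.rm = TRUE))
    return("qualified percentages must lie in [0, 100]")
  TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
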