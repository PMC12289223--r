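#' @describeIn accessors channel names of a record.
#' @export
setMethod("channelNames", "MultiChannelRecord", function(x) names(x@channels))

#' @describeIn accessors sample vector of one channel, by name or role.
#' @param which channel name, or a role (\code{"ECG"}, \code{"PPG"},
#'   \code{"ABP"}, \code{"VCP"}) resolved to the first matching channel.
#' @export
setMethod("channel", "MultiChannelRecord", function(x, which, ...) {
  x@channels[[.resolveChannel(x, which)]]
})

#' @describeIn accessors sampling rate (Hz) of one channel (or all if
#'   \code{which} is missing).
#' @export
setMethod("samplingRate", "MultiChannelRecord", function(x, which, ...) {
  if (missing(which)) return(x@fs)
  unname(x@fs[.resolveChannel(x, which)])
})

#' @describeIn accessors named role vector of a record.
#' @export
setMethod("channelRoles", "MultiChannelRecord", function(x) x@roles)

#' @describeIn accessors record duration in seconds (longest channel).
#' @export
setMethod("recordDuration", "MultiChannelRecord", function(x) {
  max(vapply(names(x@channels),
             function(nm) length(x@channels[[nm]]) / x@fs[[nm]],
             numeric(1)))
})

.resolveChannel <- function(record, which) {
  stopifnot(length(which) == 1L)
  if (which %in% names(record@channels)) return(which)
  hit <- names(record@roles)[record@roles == which]
  if (!length(hit))
    stop("no channel named or with role '", which, "'", call. = FALSE)
  hit[[1L]]
}

#' @describeIn accessors event data.frame of an [EventList-class].
#' @export
setMethod("events", "EventList", function(x) x@events)

#' @describeIn accessors events scheduled by the simulator.
#' @export
setMethod("events", "SimGroundTruth", function(x) x@events)

#' @describeIn accessors per-beat data.frame of a [BeatTable-class]
#'   (features plus \code{qualified} and semicolon-joined \code{reasons}).
#' @export
setMethod("beats", "BeatTable", function(x) {
  b <- x@beats
  b$qualified <- x@qualified
  b$reasons <- vapply(x@reasons, paste, character(1), collapse = ";")
  b
})

#' @describeIn accessors number of beats.
#' @export
setMethod("nBeats", "BeatTable", function(x) nrow(x@beats))

#' @describeIn accessors logical qualification mask per beat.
#' @export
setMethod("qualified", "BeatTable", function(x) x@qualified)

#' @describeIn accessors list of per-beat disqualification reason codes.
#' @export
setMethod("reasons", "BeatTable", function(x) x@reasons)

#' @describeIn accessors transfer gain \code{|H(f)|} per frequency bin.
#' @export
setMethod("gain", "TransferEstimate", function(x) Mod(x@H))

#' @describeIn accessors transfer phase \code{arg H(f)} in radians.
#' @export
setMethod("phase", "TransferEstimate", function(x) Arg(x@H))

#' @describeIn accessors magnitude-squared coherence per frequency bin.
#' @export
setMethod("coherence", "TransferEstimate", function(x) x@msc)

#' @describeIn accessors mean LF coherence of a [BRSIndex-class].
#' @export
setMethod("coherence", "BRSIndex", function(x) x@meanLFCoherence)

#' @describeIn accessors band-averaged BRS value.
#' @export
setMethod("brsValue", "BRSIndex", function(x) x@value)

#' @describeIn accessors coherence qualification of a window.
#' @export
setMethod("qualified", "BRSIndex", function(x) x@qualified)

#' @describeIn accessors per-beat ground-truth data.frame of a simulation.
#' @export
setMethod("groundTruth", "SimGroundTruth", function(x) {
  data.frame(t = x@t, sbp = x@sbp, rr = x@rr, pat = x@pat, rdr = x@rdr,
             trueSbp = x@trueSbp, trueRr = x@trueRr, truePat = x@truePat,
             trueRdr = x@trueRdr, trueGain = x@trueGain)
})

#' @describeIn accessors number of simulated beats.
#' @export
setMethod("nBeats", "SimGroundTruth", function(x) length(x@t))

#' @describeIn accessors 15-minute profile grid of an
#'   [AmbulatoryProfile-class].
#' @export
setMethod("profileGrid", "AmbulatoryProfile", function(x) x@grid)

setMethod("show", "MultiChannelRecord", function(object) {
  cat("MultiChannelRecord:", length(object@channels), "channel(s),",
      sprintf("%.1f s\n", recordDuration(object)))
  for (nm in names(object@channels)) {
    cat(sprintf("  %-8s [%s] %g Hz, %d samples (%s)\n", nm,
                object@roles[[nm]], object@fs[[nm]],
                length(object@channels[[nm]]), object@units[[nm]]))
  }
  invisible(object)
})

setMethod("show", "EventList", function(object) {
  cat("EventList:", nrow(object@events), "event(s)\n")
  if (nrow(object@events)) print(utils::head(object@events, 5L))
  invisible(object)
})

setMethod("show", "BeatTable", function(object) {
  cat(sprintf("BeatTable: %d beats (%s), %d qualified\n",
              nrow(object@beats),
              if (nzchar(object@modality)) object@modality else "ECG only",
              sum(object@qualified)))
  invisible(object)
})

setMethod("show", "TransferEstimate", function(object) {
  cat(sprintf(
    "TransferEstimate: %d bins, df = %.4f Hz, %d Welch segment(s)\n",
    length(object@f), if (length(object@f) > 1) diff(object@f[1:2]) else NA,
    object@nSegments))
  invisible(object)
})

setMethod("show", "BRSIndex", function(object) {
  cat(sprintf(
    "BRSIndex %s/%s: %.3f (mean LF coherence %.3f, %squalified)\n",
    object@inputFeature, object@modality, object@value,
    object@meanLFCoherence, if (object@qualified) "" else "not "))
  invisible(object)
})

setMethod("show", "SimGroundTruth", function(object) {
  cat(sprintf("SimGroundTruth: %d beats over %.1f s, mean true gain %.2f ms/mmHg\n",
              length(object@t), diff(range(object@t)),
              mean(object@trueGain)))
  invisible(object)
})

setMethod("show", "StudyResult", function(object) {
  cat("StudyResult:", length(unique(object@brs$participant)),
      "participant(s) x", length(unique(object@brs$intervention)),
      "intervention(s),", length(unique(object@brs$index)), "index/indices\n")
  invisible(object)
})

setMethod("show", "AmbulatoryProfile", function(object) {
  cat("AmbulatoryProfile:", nrow(object@grid), "grid points (15 min),",
      nrow(object@windows), "4-min windows\n")
  invisible(object)
})
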