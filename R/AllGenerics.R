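#' Accessor generics
#'
#' Small accessor family for the package's S4 containers; see the class
#' pages for semantics.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("channel", function(x, which, ...) standardGeneric("channel"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x, which, ...) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname accessors
#' @export
setGeneric("recordDuration", function(x) standardGeneric("recordDuration"))

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("beats", function(x) standardGeneric("beats"))

#' @rdname accessors
#' @export
setGeneric("nBeats", function(x) standardGeneric("nBeats"))

#' @rdname accessors
#' @export
setGeneric("qualified", function(x) standardGeneric("qualified"))

#' @rdname accessors
#' @export
setGeneric("reasons", function(x) standardGeneric("reasons"))

#' @rdname accessors
#' @export
setGeneric("gain", function(x) standardGeneric("gain"))

#' @rdname accessors
#' @export
setGeneric("phase", function(x) standardGeneric("phase"))

#' @rdname accessors
#' @export
setGeneric("coherence", function(x) standardGeneric("coherence"))

#' @rdname accessors
#' @export
setGeneric("brsValue", function(x) standardGeneric("brsValue"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("profileGrid", function(x) standardGeneric("profileGrid"))
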