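#' @name accessors
#' @title Accessors for DyadRecording and CoherenceMap
#' @description Slot accessors for the package's S4 containers.
#' @param object a \linkS4class{DyadRecording} or \linkS4class{CoherenceMap}.
#' @return The corresponding slot value (see the individual generics).
NULL

#' @rdname accessors
#' @export
setGeneric("subjectA", function(object) standardGeneric("subjectA"))
#' @rdname accessors
#' @export
setGeneric("subjectB", function(object) standardGeneric("subjectB"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelIds", function(object) standardGeneric("channelIds"))
#' @rdname accessors
#' @export
setGeneric("dyadId", function(object) standardGeneric("dyadId"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("coherenceValues", function(object) standardGeneric("coherenceValues"))
#' @rdname accessors
#' @export
setGeneric("periods", function(object) standardGeneric("periods"))
#' @rdname accessors
#' @export
setGeneric("mapTimes", function(object) standardGeneric("mapTimes"))
#' @rdname accessors
#' @export
setGeneric("coi", function(object) standardGeneric("coi"))

#' @rdname accessors
#' @export
setMethod("subjectA", "DyadRecording", function(object) object@subjectA)
#' @rdname accessors
#' @export
setMethod("subjectB", "DyadRecording", function(object) object@subjectB)
#' @rdname accessors
#' @export
setMethod("samplingRate", "DyadRecording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("channelIds", "DyadRecording", function(object) object@channelIds)
#' @rdname accessors
#' @export
setMethod("dyadId", "DyadRecording", function(object) object@dyadId)
#' @rdname accessors
#' @export
setMethod("nChannels", "DyadRecording", function(object) nrow(object@subjectA))
#' @rdname accessors
#' @export
setMethod("nSamples", "DyadRecording", function(object) ncol(object@subjectA))
#' @rdname accessors
#' @export
setMethod("duration", "DyadRecording",
          function(object) ncol(object@subjectA) / object@fs)

#' @rdname accessors
#' @export
setMethod("coherenceValues", "CoherenceMap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("periods", "CoherenceMap", function(object) object@periods)
#' @rdname accessors
#' @export
setMethod("mapTimes", "CoherenceMap", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("coi", "CoherenceMap", function(object) object@coi)

#' In-COI mask of a CoherenceMap
#'
#' Logical time x period matrix marking entries whose period is within the
#' cone of influence at that time point (edge effects negligible).
#'
#' @param object a \linkS4class{CoherenceMap}.
#' @return logical matrix of the same shape as [coherenceValues()].
#' @export
coiMask <- function(object) {
  stopifnot(is(object, "CoherenceMap"))
  outer(object@coi, object@periods, `>=`)
}

setMethod("show", "DyadRecording", function(object) {
  cat(sprintf(
    "DyadRecording '%s': %d channel(s) x %d samples @ %.3f Hz (%.1f s)\n",
    object@dyadId, nrow(object@subjectA), ncol(object@subjectA), object@fs,
    ncol(object@subjectA) / object@fs))
  invisible(NULL)
})

setMethod("show", "CoherenceMap", function(object) {
  v <- object@values[coiMask(object)]
  cat(sprintf(
    "CoherenceMap: %d time points x %d periods (%.2f-%.2f s), %.1f s span\n",
    nrow(object@values), ncol(object@values), min(object@periods),
    max(object@periods), diff(range(object@times))))
  if (length(v))
    cat(sprintf("  in-COI coherence: mean %.3f, range [%.3f, %.3f]\n",
                mean(v, na.rm = TRUE), min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  invisible(NULL)
})
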