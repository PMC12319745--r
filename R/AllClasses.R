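#' DyadRecording: paired subject signals of one dyad
#'
#' Holds the two channel-by-sample signal matrices of one dyad, their common
#' sampling rate and channel labels. Both members must have identical shape
#' and contain no missing samples.
#'
#' @slot subjectA numeric matrix, channels x samples, first dyad member.
#' @slot subjectB numeric matrix, channels x samples, second dyad member.
#' @slot fs sampling rate in Hz.
#' @slot channelIds character vector of channel labels, one per row.
#' @slot dyadId single identifier string.
#'
#' @seealso [dyadRecording()] for the constructor,
#'   [subjectA()], [subjectB()], [samplingRate()], [channelIds()],
#'   [dyadId()], [nChannels()], [nSamples()], [duration()].
#' @export
setClass("DyadRecording",
  representation(
    subjectA   = "matrix",
    subjectB   = "matrix",
    fs         = "numeric",
    channelIds = "character",
    dyadId     = "character"
  )
)

setValidity("DyadRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@subjectA) || !is.numeric(object@subjectB))
    msg <- c(msg, "subject matrices must be numeric")
  if (!identical(dim(object@subjectA), dim(object@subjectB)))
    msg <- c(msg, "both subjects must have identical channels x samples shape")
  if (anyNA(object@subjectA) || anyNA(object@subjectB))
    msg <- c(msg, "recordings must not contain missing samples")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channelIds) != nrow(object@subjectA))
    msg <- c(msg, "channelIds must have one label per channel row")
  if (length(object@dyadId) != 1L)
    msg <- c(msg, "dyadId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a DyadRecording
#'
#' @param subjectA,subjectB channels x samples numeric matrices (a bare
#'   numeric vector is treated as a single channel).
#' @param fs sampling rate in Hz.
#' @param channelIds channel labels; defaults to `"ch1"`, `"ch2"`, ...
#' @param dyadId identifier for the dyad.
#' @return A \linkS4class{DyadRecording}.
#' @examples
#' rec <- dyadRecording(rnorm(100), rnorm(100), fs = 7.81, dyadId = "d01")
#' duration(rec)
#' @export
dyadRecording <- function(subjectA, subjectB, fs,
                          channelIds = NULL, dyadId = "dyad") {
  if (is.vector(subjectA)) subjectA <- matrix(subjectA, nrow = 1L)
  if (is.vector(subjectB)) subjectB <- matrix(subjectB, nrow = 1L)
  if (is.null(channelIds)) channelIds <- paste0("ch", seq_len(nrow(subjectA)))
  new("DyadRecording",
      subjectA = subjectA, subjectB = subjectB, fs = as.numeric(fs),
      channelIds = as.character(channelIds), dyadId = as.character(dyadId))
}

#' CoherenceMap: time x period wavelet coherence matrix
#'
#' Squared wavelet coherence over a time and period grid, together with the
#' per-time-point cone of influence (COI): the largest period whose edge
#' exclusion zone does not reach that time point. Values are in [0, 1]
#' (NaN where the smoothed spectra are degenerate).
#'
#' @slot values numeric matrix, time x period, coherence in [0, 1].
#' @slot periods ascending periods in seconds, one per column.
#' @slot times sample times in seconds, one per row.
#' @slot coi per-time-point maximum valid period in seconds.
#'
#' @seealso [waveletCoherence()], [coherenceValues()], [periods()],
#'   [mapTimes()], [coi()], [coiMask()].
#' @export
setClass("CoherenceMap",
  representation(
    values  = "matrix",
    periods = "numeric",
    times   = "numeric",
    coi     = "numeric"
  )
)

setValidity("CoherenceMap", function(object) {
  msg <- character()
  v <- object@values
  if (ncol(v) != length(object@periods))
    msg <- c(msg, "one period per column required")
  if (nrow(v) != length(object@times))
    msg <- c(msg, "one time per row required")
  if (length(object@coi) != nrow(v))
    msg <- c(msg, "one COI value per time point required")
  if (is.unsorted(object@periods, strictly = TRUE))
    msg <- c(msg, "periods must be strictly ascending")
  fin <- v[is.finite(v)]
  if (length(fin) && (min(fin) < -1e-10 || max(fin) > 1 + 1e-10))
    msg <- c(msg, "coherence values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

coherenceMap <- function(values, periods, times, coi) {
  new("CoherenceMap", values = values, periods = as.numeric(periods),
      times = as.numeric(times), coi = as.numeric(coi))
}
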