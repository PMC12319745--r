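# Window planning, band averaging with Mayer censoring, COI trimming and
# the per-dyad task-vs-rest coherence contrast.

# time-to-sample conventions: floor for window starts/ends (half-open
# [start, end) intervals), ceiling for trims; samples are 0-based in time
# `i / fs` and stored 1-based.

#' Band-averaged coherence with Mayer-wave censoring
#'
#' Unweighted mean of the coherence map over grid periods inside
#' `[bandLo, censorLo]` or `[censorHi, bandHi]` (endpoints retained, the
#' censored interior excluded), per time point.
#'
#' @param map a \linkS4class{CoherenceMap}.
#' @param band a [bandSpec()].
#' @return Numeric series, one value per time point of the map.
#' @export
censoredBandMean <- function(map, band = bandSpec()) {
  stopifnot(is(map, "CoherenceMap"), is(band, "BandSpec"))
  p <- map@periods
  sel <- (p >= band$bandLo & p <= band$censorLo) |
         (p >= band$censorHi & p <= band$bandHi)
  if (!any(sel)) stop("no grid periods inside the band")
  rowMeans(map@values[, sel, drop = FALSE])
}

#' Plan non-overlapping task windows
#'
#' The first window starts `offset` seconds into the task phase; each
#' subsequent window starts `offset` after the previous one ends; windows
#' lie wholly inside the task phase and the count is maximal.
#'
#' @param taskStart,taskEnd task phase limits in seconds.
#' @param length window duration in seconds (> 0).
#' @param offset gap in seconds (>= 0).
#' @return Matrix with columns `start`, `end` (half-open intervals in
#'   seconds); zero rows if nothing fits.
#' @examples
#' planTaskWindows(60, 300, 50, 8)  # 4 windows: 68, 126, 184, 242 s
#' @export
planTaskWindows <- function(taskStart, taskEnd, length, offset = 8) {
  stopifnot(length > 0, offset >= 0)
  starts <- numeric()
  s <- taskStart + offset
  while (s + length <= taskEnd) {
    starts <- c(starts, s)
    s <- s + length + offset
  }
  cbind(start = starts, end = starts + length)
}

#' COI-trimmed mean over a window
#'
#' Mean of a per-time series over `[start + trim, end - trim)`, with the
#' window mapped to samples by flooring and the trim by ceiling.
#'
#' @param series numeric series whose first sample is time 0.
#' @param fs sampling rate in Hz.
#' @param window numeric `c(start, end)` in seconds.
#' @param trim per-end trim in seconds; the window must be longer than
#'   `2 * trim`.
#' @return Scalar mean.
#' @export
trimmedWindowMean <- function(series, fs, window, trim) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  if (window[2] - window[1] <= 2 * trim)
    stop("window too short after COI trimming")
  s0 <- floor(window[1] * fs)
  s1 <- floor(window[2] * fs)
  tr <- ceiling(trim * fs)
  lo <- s0 + tr + 1L
  hi <- s1 - tr
  if (hi < lo || hi > length(series))
    stop("window too short after COI trimming")
  mean(series[lo:hi])
}

resolveTrim <- function(scheme, band, params) {
  if (is.null(scheme$trim)) coiSeconds(band$bandHi, params) else scheme$trim
}

# excise samples of [start, end) seconds from a row of a recording
exciseSegment <- function(sig, fs, start, end) {
  i0 <- floor(start * fs) + 1L
  i1 <- floor(end * fs)
  sig[i0:i1]
}

segmentBandSeries <- function(a, b, fs, start, end, band, params) {
  xs <- exciseSegment(a, fs, start, end)
  ys <- exciseSegment(b, fs, start, end)
  censoredBandMean(waveletCoherence(xs, ys, fs, band, params), band)
}

# hot-path variant: precomputed grid/selection, no CoherenceMap object
bandSeriesClosure <- function(fs, band, params) {
  margin <- ceiling(0.6 / (2 / params$voicesPerOctave)) + 1L
  grid <- buildScaleGrid(band$bandLo, band$bandHi, params, fs,
                         marginVoices = margin)
  p <- grid$periods
  sel <- (p >= band$bandLo & p <= band$censorLo) |
         (p >= band$censorHi & p <= band$bandHi)
  scalesSamp <- grid$scales * fs
  selIdx <- which(sel) - 1L
  function(xs, ys) {
    as.numeric(.wtcBandCore(xs, ys, scalesSamp, params$omega0, grid$dj,
                            selIdx))
  }
}

#' Windowed task-vs-rest coherence contrast for one dyad
#'
#' Computes, per channel (homologous channels of the two subjects are
#' paired), the Fisher-z coherence contrast between task windows and the
#' immediately preceding rest phase, in up to three modes:
#' \describe{
#'   \item{windowed}{each planned task window is excised and
#'     wavelet-transformed on its own (as a real-time system must); the
#'     rest baseline is likewise the excised rest phase.}
#'   \item{complete}{the entire task phase excised and transformed as one
#'     window, against the excised rest phase.}
#'   \item{offline}{one coherence computation over the full recording,
#'     with task/rest segment means taken afterwards (the conventional
#'     whole-time-course analysis).}
#' }
#' All means are censored band means ([censoredBandMean()]) trimmed by the
#' COI on both window ends ([trimmedWindowMean()]); the rest baseline is
#' trimmed the same way.
#'
#' @param dyad a \linkS4class{DyadRecording}.
#' @param layout a [phaseLayout()] or list of them (one per block; each
#'   block's windows are referenced to that block's preceding rest).
#' @param scheme a [windowScheme()].
#' @param band a [bandSpec()].
#' @param params a [morletParams()].
#' @return data.frame with columns `dyadId`, `channelId`, `block`, `mode`
#'   (window length in seconds as `"50s"` etc., `"complete"`, or
#'   `"offline"`), `windowIndex`, `wtcTask`, `wtcRest`, `deltaZ`
#'   (`atanh(wtcTask - wtcRest)`).
#' @export
windowWtcForDyad <- function(dyad, layout, scheme = windowScheme(),
                             band = bandSpec(), params = morletParams()) {
  stopifnot(is(dyad, "DyadRecording"))
  if (is(layout, "PhaseLayout")) layout <- list(layout)
  fs <- dyad@fs
  trim <- resolveTrim(scheme, band, params)
  if (length(scheme$lengths) && min(scheme$lengths) <= 2 * trim)
    stop("shortest window does not exceed twice the COI trim")
  nTot <- nSamples(dyad)
  bandSeries <- bandSeriesClosure(fs, band, params)
  rowMode <- character(); rowCh <- character(); rowBlock <- integer()
  rowIdx <- integer(); rowTask <- numeric(); rowRest <- numeric()
  for (ch in seq_len(nChannels(dyad))) {
    a <- dyad@subjectA[ch, ]
    b <- dyad@subjectB[ch, ]
    offlineSeries <- if (scheme$offline) bandSeries(a, b)
    for (bi in seq_along(layout)) {
      lay <- layout[[bi]]
      stopifnot(lay$taskEnd <= nTot / fs + 1 / fs)
      segMean <- function(start, end) {
        s <- bandSeries(exciseSegment(a, fs, start, end),
                        exciseSegment(b, fs, start, end))
        trimmedWindowMean(s, fs, c(0, end - start), trim)
      }
      restSeg <- segMean(lay$restStart, lay$restEnd)
      addRow <- function(mode, idx, task, rest) {
        k <- length(rowMode) + 1L
        rowMode[k] <<- mode; rowCh[k] <<- dyad@channelIds[ch]
        rowBlock[k] <<- bi; rowIdx[k] <<- idx
        rowTask[k] <<- task; rowRest[k] <<- rest
      }
      for (len in scheme$lengths) {
        wins <- planTaskWindows(lay$taskStart, lay$taskEnd, len,
                                scheme$offset)
        for (k in seq_len(nrow(wins)))
          addRow(sprintf("%gs", len), k,
                 segMean(wins[k, 1], wins[k, 2]), restSeg)
      }
      if (scheme$completeBlock)
        addRow("complete", 1L, segMean(lay$taskStart, lay$taskEnd), restSeg)
      if (scheme$offline) {
        taskOff <- trimmedWindowMean(offlineSeries, fs,
                                     c(lay$taskStart, lay$taskEnd), trim)
        restOff <- trimmedWindowMean(offlineSeries, fs,
                                     c(lay$restStart, lay$restEnd), trim)
        addRow("offline", 1L, taskOff, restOff)
      }
    }
  }
  data.frame(dyadId = dyad@dyadId, channelId = rowCh, block = rowBlock,
             mode = rowMode, windowIndex = rowIdx, wtcTask = rowTask,
             wtcRest = rowRest, deltaZ = fisherZ(rowTask - rowRest),
             stringsAsFactors = FALSE)
}
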