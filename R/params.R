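# Validated parameter records. These are light S3 records in the style of
# Bioconductor parameter objects; all fields are checked at construction.

recordClass <- function(x, cls) structure(x, class = c(cls, "hyperibsParams"))

#' @export
print.hyperibsParams <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1L]))
  flat <- x[!vapply(x, is.list, logical(1L))]
  for (nm in names(flat))
    cat(sprintf("  %s: %s\n", nm, paste(format(flat[[nm]]), collapse = ", ")))
  for (nm in names(x)[vapply(x, is.list, logical(1L))])
    cat(sprintf("  %s: <%s>\n", nm, class(x[[nm]])[1L]))
  invisible(x)
}

#' Block/event design of one simulated recording
#'
#' One rest-task-rest block: an initial rest phase, a train of task events at
#' a fixed intertrial interval, and a closing rest phase. The defaults are a
#' 60 s rest, 30 events 8 s apart (a 240 s task phase) and a 60 s rest,
#' sampled at 7.81 Hz, mirroring a timed dyadic game design.
#'
#' @param restPre initial rest duration in seconds.
#' @param nEvents number of task events (>= 0).
#' @param iti intertrial interval in seconds.
#' @param restPost closing rest duration in seconds.
#' @param fs sampling rate in Hz.
#' @return A `DesignSpec` record; `totalDuration` is
#'   `restPre + nEvents * iti + restPost`.
#' @examples
#' d <- designSpec()
#' d$totalDuration  # 360 s
#' @export
designSpec <- function(restPre = 60, nEvents = 30, iti = 8, restPost = 60,
                       fs = 7.81) {
  stopifnot(restPre > 0, restPost > 0, iti > 0, nEvents >= 0, fs > 0)
  recordClass(list(
    restPre = restPre, nEvents = as.integer(nEvents), iti = iti,
    restPost = restPost, fs = fs,
    totalDuration = restPre + nEvents * iti + restPost
  ), "DesignSpec")
}

#' Canonical double-gamma hemodynamic response parameters
#'
#' The canonical double-gamma HRF: a gamma-density peak minus a scaled
#' gamma-density undershoot. Defaults are the widely used canonical values
#' (peak delay 6 s, undershoot delay 16 s, unit dispersions, 1:6
#' peak-to-undershoot ratio, 32 s kernel).
#'
#' @param peakDelay,undershootDelay response/undershoot delays in seconds.
#' @param peakDispersion,undershootDispersion dispersions in seconds (> 0).
#' @param peakUndershootRatio dimensionless ratio; `Inf` removes the
#'   undershoot entirely.
#' @param kernelLength kernel duration in seconds (> peakDelay).
#' @return An `HrfParams` record.
#' @export
hrfParams <- function(peakDelay = 6, undershootDelay = 16,
                      peakDispersion = 1, undershootDispersion = 1,
                      peakUndershootRatio = 6, kernelLength = 32) {
  stopifnot(peakDispersion > 0, undershootDispersion > 0,
            kernelLength > peakDelay, peakUndershootRatio > 0)
  recordClass(list(
    peakDelay = peakDelay, undershootDelay = undershootDelay,
    peakDispersion = peakDispersion,
    undershootDispersion = undershootDispersion,
    peakUndershootRatio = peakUndershootRatio,
    kernelLength = kernelLength
  ), "HrfParams")
}

#' Simulation configuration for a dyad cohort
#'
#' @param design a [designSpec()].
#' @param hrf an [hrfParams()].
#' @param snrDb signal-to-noise ratio in dB (power ratio over the whole
#'   simulated time course). `-Inf` yields pure unit-variance noise dyads
#'   with no activation (the null condition).
#' @param nDyads dyads per iteration (>= 2).
#' @param nIterations number of cohort iterations (>= 1).
#' @param seed master RNG seed; per-iteration and per-dyad child seeds are
#'   derived from it deterministically.
#' @return A `SimConfig` record.
#' @export
simConfig <- function(design = designSpec(), hrf = hrfParams(),
                      snrDb = 1.90, nDyads = 25, nIterations = 50,
                      seed = 1L) {
  stopifnot(nDyads >= 2, nIterations >= 1)
  recordClass(list(
    design = design, hrf = hrf, snrDb = snrDb,
    nDyads = as.integer(nDyads), nIterations = as.integer(nIterations),
    seed = as.integer(seed)
  ), "SimConfig")
}

#' Morlet wavelet parameters
#'
#' @param omega0 dimensionless center frequency of the Morlet wavelet.
#' @param voicesPerOctave number of scales per period doubling (>= 1).
#' @return A `MorletParams` record.
#' @export
morletParams <- function(omega0 = 6, voicesPerOctave = 14L) {
  stopifnot(omega0 > 0, voicesPerOctave >= 1)
  recordClass(list(omega0 = omega0,
                   voicesPerOctave = as.integer(voicesPerOctave)),
              "MorletParams")
}

#' Period band of interest with Mayer-wave censoring
#'
#' The coherence band average runs over periods in
#' `[bandLo, censorLo]` and `[censorHi, bandHi]` (endpoints retained); the
#' censored interior excludes ~0.1 Hz Mayer-wave periods that can
#' synchronize spuriously through blood-pressure oscillations.
#'
#' @param bandLo,bandHi band limits in seconds.
#' @param censorLo,censorHi censored sub-band in seconds.
#' @return A `BandSpec` record.
#' @export
bandSpec <- function(bandLo = 6, bandHi = 14, censorLo = 9, censorHi = 11) {
  stopifnot(bandLo < censorLo, censorLo < censorHi, censorHi < bandHi,
            bandLo > 0)
  recordClass(list(bandLo = bandLo, bandHi = bandHi,
                   censorLo = censorLo, censorHi = censorHi), "BandSpec")
}

#' Task-window scheme for the short-window analysis
#'
#' @param lengths window durations in seconds.
#' @param offset gap in seconds before the first window and between windows
#'   (accounts for hemodynamic delay and keeps windows independent).
#' @param trim per-end COI trim in seconds; `NULL` means
#'   [coiSeconds()] of the band's largest period, resolved at analysis time.
#' @param completeBlock,offline include the complete-block / offline modes.
#' @return A `WindowScheme` record.
#' @export
windowScheme <- function(lengths = c(50, 60, 70, 80, 90, 100), offset = 8,
                         trim = NULL, completeBlock = TRUE, offline = TRUE) {
  stopifnot(all(lengths > 0), offset >= 0)
  if (!is.null(trim)) {
    stopifnot(trim >= 0, min(lengths) > 2 * trim)
  }
  recordClass(list(lengths = lengths, offset = offset, trim = trim,
                   completeBlock = isTRUE(completeBlock),
                   offline = isTRUE(offline)), "WindowScheme")
}

#' Rest/task phase layout of one block
#'
#' @param restStart,restEnd,taskStart,taskEnd phase boundaries in seconds;
#'   the rest phase must immediately precede the task phase it baselines.
#' @return A `PhaseLayout` record.
#' @export
phaseLayout <- function(restStart = 0, restEnd = 60, taskStart = 60,
                        taskEnd = 300) {
  stopifnot(restStart < restEnd, restEnd <= taskStart, taskStart < taskEnd)
  recordClass(list(restStart = restStart, restEnd = restEnd,
                   taskStart = taskStart, taskEnd = taskEnd), "PhaseLayout")
}

#' Layout implied by a simulation design
#'
#' @param design a [designSpec()].
#' @return A [phaseLayout()] covering the design's rest and task phases.
#' @export
layoutFromDesign <- function(design) {
  phaseLayout(0, design$restPre, design$restPre,
              design$restPre + design$nEvents * design$iti)
}

#' Channel quality-control parameters
#'
#' @param sdRange admissible source-detector distance range in mm.
#' @param snrThresh minimum mean/std of raw intensity.
#' @param dRange admissible mean raw-intensity range (dataset specific;
#'   0.01-2.5 suits short-separation NIRScout-style recordings, 0.01-4
#'   ETG-style ones).
#' @return A `QcParams` record.
#' @export
qcParams <- function(sdRange = c(20, 45), snrThresh = 2,
                     dRange = c(0.01, 2.5)) {
  stopifnot(length(sdRange) == 2L, sdRange[1] < sdRange[2],
            length(dRange) == 2L, dRange[1] < dRange[2], snrThresh > 0)
  recordClass(list(sdRange = sdRange, snrThresh = snrThresh,
                   dRange = dRange), "QcParams")
}

#' Modified Beer-Lambert parameters
#'
#' @param ppf partial pathlength factor (dimensionless).
#' @param extinction chromophore x wavelength extinction coefficients in
#'   cm^-1 mM^-1; defaults to [extinctionTable()].
#' @return An `MbllParams` record.
#' @export
mbllParams <- function(ppf = 6, extinction = extinctionTable()) {
  stopifnot(ppf > 0, is.matrix(extinction), nrow(extinction) == 2L)
  recordClass(list(ppf = ppf, extinction = extinction), "MbllParams")
}

#' Hemoglobin extinction coefficients
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the
#' wavelengths used by common fNIRS systems, in cm^-1 mM^-1, compiled from
#' the standard tabulated spectra (Prahl's compilation of Gratzer's data).
#'
#' @return 2 x 4 matrix, rows `HbO`/`HbR`, columns wavelengths in nm.
#' @export
extinctionTable <- function() {
  m <- rbind(
    HbO = c(0.3123, 0.5862, 0.9744, 1.0580),
    HbR = c(1.9317, 1.5485, 0.6930, 0.6913)
  )
  colnames(m) <- c("695", "760", "830", "850")
  m
}
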