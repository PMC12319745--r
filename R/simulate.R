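#' Unit-impulse event vector for a block design
#'
#' @param design a [designSpec()].
#' @return Numeric vector of length `round(totalDuration * fs)` with unit
#'   impulses at event onsets: the first at `restPre`, subsequent onsets
#'   spaced by `iti` (onset times mapped to samples by flooring).
#' @examples
#' ev <- buildEventVector(designSpec())
#' length(ev)  # 2812 at 7.81 Hz
#' @export
buildEventVector <- function(design) {
  stopifnot(is(design, "DesignSpec"))
  if (design$fs <= 0) stop("sampling rate must be positive")
  n <- round(design$totalDuration * design$fs)
  ev <- numeric(n)
  if (design$nEvents > 0L) {
    onsets <- design$restPre + design$iti * (seq_len(design$nEvents) - 1L)
    idx <- floor(onsets * design$fs) + 1L
    if (any(idx > n)) stop("event onsets fall outside the recording")
    ev[idx] <- 1
  }
  ev
}

#' Double-gamma hemodynamic response kernel
#'
#' Difference of two gamma densities (peak minus undershoot divided by the
#' peak-to-undershoot ratio), sampled at `fs` over the kernel length and
#' normalized to a peak value of 1.
#'
#' @param hrf an [hrfParams()].
#' @param fs sampling rate in Hz.
#' @return Numeric vector of `round(kernelLength * fs)` samples.
#' @examples
#' k <- hrfKernel(hrfParams(), fs = 10)
#' length(k)  # 320
#' @export
hrfKernel <- function(hrf, fs) {
  stopifnot(is(hrf, "HrfParams"), fs > 0)
  t <- (seq_len(round(hrf$kernelLength * fs)) - 1L) / fs
  peak <- dgamma(t, shape = hrf$peakDelay / hrf$peakDispersion,
                 scale = hrf$peakDispersion)
  under <- if (is.infinite(hrf$peakUndershootRatio)) 0 else
    dgamma(t, shape = hrf$undershootDelay / hrf$undershootDispersion,
           scale = hrf$undershootDispersion) / hrf$peakUndershootRatio
  k <- peak - under
  k / max(k)
}

#' Noise-free simulated time course
#'
#' Convolution of the design's event vector with the HRF kernel, truncated
#' to the design length. Identically zero before the first event onset.
#'
#' @param design a [designSpec()].
#' @param hrf an [hrfParams()].
#' @return Numeric vector, one sample per design sample.
#' @export
simulateCleanSignal <- function(design, hrf = hrfParams()) {
  ev <- buildEventVector(design)
  k <- hrfKernel(hrf, design$fs)
  # direct sparse convolution: exact zeros before the first onset
  y <- numeric(length(ev))
  for (i in which(ev != 0)) {
    j <- i:min(length(y), i + length(k) - 1L)
    y[j] <- y[j] + ev[i] * k[seq_along(j)]
  }
  y
}

#' Add Gaussian noise at a target SNR
#'
#' Adds i.i.d. Gaussian noise with variance
#' `var(clean) / 10^(snrDb / 10)`, so the realized power ratio converges to
#' the target SNR as the series grows. SNR is defined over the entire time
#' course, rest phases included.
#'
#' @param clean noise-free series (non-zero variance unless `snrDb` is
#'   infinite).
#' @param snrDb target SNR in dB; `Inf` returns `clean` unchanged.
#' @return `clean` plus the noise draw.
#' @export
addNoiseAtSnr <- function(clean, snrDb) {
  if (is.infinite(snrDb) && snrDb > 0) return(clean)
  v <- var(clean)
  if (!is.finite(v) || v <= 0)
    stop("clean signal has zero variance; finite target SNR is undefined")
  sigma <- sqrt(v / 10^(snrDb / 10))
  clean + rnorm(length(clean), 0, sigma)
}

# Deterministic child seeds below 2^31, derived from one master seed.
childSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a cohort of dyads
#'
#' For every iteration, generates `nDyads` recordings in which both dyad
#' members share one clean HRF-convolved activation (the synchrony source)
#' and receive independent Gaussian noise at the configured SNR. With
#' `snrDb = -Inf` the activation is absent and both members are pure
#' unit-variance noise (null dyads). Fully deterministic given the seed.
#'
#' @param cfg a [simConfig()].
#' @return List with one element per iteration, each a list of
#'   \linkS4class{DyadRecording} objects.
#' @examples
#' cohort <- simulateCohort(simConfig(nDyads = 2, nIterations = 1))
#' cohort[[1]][[1]]
#' @export
simulateCohort <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  nullMode <- is.infinite(cfg$snrDb) && cfg$snrDb < 0
  clean <- if (nullMode) {
    numeric(round(cfg$design$totalDuration * cfg$design$fs))
  } else {
    simulateCleanSignal(cfg$design, cfg$hrf)
  }
  seeds <- matrix(childSeeds(cfg$seed, cfg$nIterations * cfg$nDyads),
                  nrow = cfg$nIterations)
  lapply(seq_len(cfg$nIterations), function(it) {
    lapply(seq_len(cfg$nDyads), function(d) {
      set.seed(seeds[it, d])
      if (nullMode) {
        a <- rnorm(length(clean))
        b <- rnorm(length(clean))
      } else {
        a <- addNoiseAtSnr(clean, cfg$snrDb)
        b <- addNoiseAtSnr(clean, cfg$snrDb)
      }
      dyadRecording(a, b, fs = cfg$design$fs,
                    dyadId = sprintf("dyad%02d", d))
    })
  })
}

#' Two-wavelength raw-intensity fixture with known artifacts
#'
#' Builds a synthetic raw-intensity dyad recording for exercising the
#' preprocessing chain, with ground truth returned alongside. Per channel
#' and wavelength the optical density is composed of a task signal (scaled
#' HRF-convolved events mapped through the Beer-Lambert forward model), a
#' shared ~0.1 Hz sinusoidal systemic component with a fixed spatial
#' loading across channels, spike and baseline-shift motion artifacts at
#' known times, and white noise; raw intensity is
#' `baseline * exp(-OD)`.
#'
#' @param nChannels number of channel sites (>= 2).
#' @param fs sampling rate in Hz.
#' @param design a [designSpec()] defining the time base and task events.
#' @param artifactSpec list with optional entries `spikeTimes` (s),
#'   `spikeAmp` (OD units), `spikeWidth` (s), `stepTimes` (s), `stepAmp`
#'   (OD units), `systemicAmp` (OD units; 0 disables the systemic wave),
#'   `systemicFreq` (Hz), `noiseSd` (OD units).
#' @param seed RNG seed.
#' @return List: `recording` (raw-intensity \linkS4class{DyadRecording},
#'   rows channel x wavelength), `geometry` (data.frame: rowId, channel,
#'   source, detector, distanceMm, wavelengthNm), and `truth` (list with
#'   the injected `task` series, per-subject clean OD matrices
#'   (`odCleanA`, `odCleanB`: task + noise, before systemic/artifacts),
#'   `systemicLoading`, `spikeTimes`, `stepTimes`, per-subject systemic
#'   series, and the HbO/HbR amplitudes used).
#' @export
makePreprocessingFixture <- function(nChannels = 4, fs = 7.81,
                                     design = designSpec(fs = fs),
                                     artifactSpec = list(), seed = 1L) {
  stopifnot(nChannels >= 2)
  spec <- modifyList(list(
    spikeTimes = numeric(), spikeAmp = 0.05, spikeWidth = 1.0,
    stepTimes = numeric(), stepAmp = 0.05,
    systemicAmp = 0.01, systemicFreq = 0.1, noiseSd = 0.001
  ), artifactSpec)
  set.seed(seed)
  n <- round(design$totalDuration * fs)
  t <- (seq_len(n) - 1L) / fs
  task <- simulateCleanSignal(design)

  wl <- c(760, 850)
  E <- extinctionTable()[, as.character(wl)]  # 2x2, rows HbO/HbR
  distMm <- 30
  ppf <- 6
  # per-channel hemodynamics: HbO up, HbR down, in mM
  hbAmp <- c(HbO = 1e-3, HbR = -4e-4)
  odTask <- (t(E) %*% hbAmp) * (distMm / 10) * ppf  # per wavelength, OD units

  loading <- rnorm(nChannels)
  loading <- loading / sqrt(sum(loading^2))
  sysWave <- function() spec$systemicAmp *
    sin(2 * pi * spec$systemicFreq * t + runif(1, 0, 2 * pi))

  art <- numeric(n)
  for (ts in spec$spikeTimes) {
    i0 <- floor(ts * fs) + 1L
    w <- max(1L, round(spec$spikeWidth * fs))
    idx <- i0:min(n, i0 + w - 1L)
    art[idx] <- art[idx] + spec$spikeAmp
  }
  for (ts in spec$stepTimes) {
    i0 <- floor(ts * fs) + 1L
    art[i0:n] <- art[i0:n] + spec$stepAmp
  }

  buildSubject <- function() {
    sys <- sysWave()
    odClean <- matrix(0, nChannels * 2L, n)
    od <- matrix(0, nChannels * 2L, n)
    for (ch in seq_len(nChannels)) {
      for (w in 1:2) {
        r <- (ch - 1L) * 2L + w
        noise <- rnorm(n, 0, spec$noiseSd)
        odClean[r, ] <- odTask[w] * task + noise
        od[r, ] <- odClean[r, ] + loading[ch] * sys + art
      }
    }
    list(od = od, odClean = odClean, sys = sys)
  }
  sa <- buildSubject()
  sb <- buildSubject()
  i0 <- 1.0
  rowIds <- as.vector(t(outer(seq_len(nChannels), wl,
                              function(c, w) sprintf("S%dD%d-%d", c, c, w))))
  geometry <- data.frame(
    rowId = rowIds,
    channel = rep(seq_len(nChannels), each = 2L),
    source = rep(seq_len(nChannels), each = 2L),
    detector = rep(seq_len(nChannels), each = 2L),
    distanceMm = distMm,
    wavelengthNm = rep(wl, nChannels),
    stringsAsFactors = FALSE
  )
  rec <- dyadRecording(i0 * exp(-sa$od), i0 * exp(-sb$od), fs = fs,
                       channelIds = rowIds, dyadId = "fixture")
  list(
    recording = rec,
    geometry = geometry,
    truth = list(task = task, odCleanA = sa$odClean, odCleanB = sb$odClean,
                 systemicLoading = loading, systemicA = sa$sys,
                 systemicB = sb$sys, spikeTimes = spec$spikeTimes,
                 stepTimes = spec$stepTimes, hbAmp = hbAmp,
                 distanceMm = distMm, ppf = ppf, wavelengths = wl)
  )
}
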