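#' Logarithmic scale grid for the Morlet CWT
#'
#' Builds a period grid with `voicesPerOctave` points per octave starting at
#' `bandLo` and extending until `bandHi` is covered, optionally with extra
#' margin voices on both sides (used internally so that scale smoothing at
#' the band edges is unbiased). Periods are converted to wavelet scales via
#' `scale = period * omega0 / (2 * pi)`, the convention under which the
#' closed-form COI of [coiSeconds()] is exact.
#'
#' @param bandLo,bandHi band limits in seconds (`0 < bandLo < bandHi`).
#' @param params a [morletParams()].
#' @param fs sampling rate in Hz.
#' @param marginVoices extra grid points added below/above the band.
#' @return A `ScaleGrid` record: `periods` (s), `scales` (s), `fs`, `dj`
#'   (scale step in octaves), and `inBand` (logical, inside
#'   `[bandLo, bandHi]`).
#' @examples
#' g <- buildScaleGrid(6, 12, morletParams(), fs = 7.81)
#' length(g$periods)  # 15: one octave at 14 voices, endpoints inclusive
#' @export
buildScaleGrid <- function(bandLo, bandHi, params = morletParams(), fs,
                           marginVoices = 0L) {
  stopifnot(is(params, "MorletParams"), bandLo > 0, bandLo < bandHi, fs > 0)
  if (bandLo * fs < 2)
    stop("band periods are below the two-sample resolution limit at this fs")
  nvo <- params$voicesPerOctave
  kmax <- ceiling(nvo * log2(bandHi / bandLo))
  k <- seq.int(-marginVoices, kmax + marginVoices)
  periodsS <- bandLo * 2^(k / nvo)
  recordClass(list(
    periods = periodsS,
    scales = periodsS * params$omega0 / (2 * pi),
    fs = fs,
    dj = 1 / nvo,
    inBand = periodsS >= bandLo & periodsS <= bandHi
  ), "ScaleGrid")
}

#' Cone-of-influence length for a period
#'
#' Per-end edge-exclusion zone, in seconds, of the Morlet wavelet at a given
#' period: `sqrt(2) * omega0 * period / (2 * pi)`. Coherence values closer
#' than this to either end of a segment are contaminated by boundary
#' effects and are discarded by the window trimming.
#'
#' @param period period in seconds (>= 0); vectorized.
#' @param params a [morletParams()].
#' @return COI length(s) in seconds.
#' @examples
#' coiSeconds(14)  # 18.90 s: why 50 s is the minimal usable window
#' @export
coiSeconds <- function(period, params = morletParams()) {
  if (any(period < 0)) stop("period must be non-negative")
  sqrt(2) * params$omega0 * period / (2 * pi)
}

padLength <- function(n, maxScaleSamples) {
  # wavelet/Gaussian tails decay as exp(-t^2 / (2 sigma^2)), sigma <= scale;
  # 4 scales of padding keeps circular wrap below ~3e-4
  2^ceiling(log2(n + ceiling(4 * maxScaleSamples)))
}

#' Morlet continuous wavelet transform
#'
#' Analytic Morlet CWT computed in the frequency domain with zero padding,
#' using the energy-preserving per-scale normalization. Linear in its
#' input.
#'
#' @param x finite numeric series.
#' @param grid a `ScaleGrid` from [buildScaleGrid()].
#' @param params a [morletParams()].
#' @return Complex matrix, time x period (rows follow `x`, columns
#'   `grid$periods`).
#' @export
cwtMorlet <- function(x, grid, params = morletParams()) {
  stopifnot(is(grid, "ScaleGrid"))
  if (anyNA(x) || !all(is.finite(x))) stop("input contains NaN/Inf samples")
  scalesSamp <- grid$scales * grid$fs
  if (length(x) < 4) stop("series too short for the requested scales")
  npad <- padLength(length(x), max(scalesSamp))
  .cwtCore(as.numeric(x), scalesSamp, params$omega0, npad)
}

#' Smoothed wavelet transform coherence of two series
#'
#' Squared wavelet coherence
#' `|S(Wx conj(Wy) / s)|^2 / (S(|Wx|^2 / s) S(|Wy|^2 / s))` with the
#' standard two-stage smoothing `S`: per-scale Gaussian time smoothing with
#' std `scale / sqrt(2)` (the squared Morlet envelope), then a boxcar
#' across scales spanning 0.6 octaves. Boundary handling follows the
#' established wavelet-coherence toolboxes: each series is
#' reflection-extended by half its length before the transform, and the
#' smoothing operates on a next-power-of-two FFT buffer, which is circular
#' for short segments. Without smoothing, coherence is identically 1 (the
#' textbook degeneracy), so smoothing is always on in analysis use.
#'
#' @param x,y equal-length finite numeric series with common sampling rate.
#' @param fs sampling rate in Hz.
#' @param band a [bandSpec()]; the internal scale grid covers it with
#'   margin voices so scale smoothing at the band edges is unbiased.
#' @param params a [morletParams()].
#' @param grid optional `ScaleGrid` overriding the band-derived grid.
#' @param smooth set `FALSE` only to demonstrate the degeneracy.
#' @return A \linkS4class{CoherenceMap} over the grid periods.
#' @examples
#' x <- sin(2 * pi * (0:799) / 7.81 / 8) + rnorm(800, 0, 0.3)
#' y <- sin(2 * pi * (0:799) / 7.81 / 8) + rnorm(800, 0, 0.3)
#' m <- waveletCoherence(x, y, fs = 7.81)
#' m
#' @export
waveletCoherence <- function(x, y, fs, band = bandSpec(),
                             params = morletParams(), grid = NULL,
                             smooth = TRUE) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("input contains NaN/Inf samples")
  if (var(x) == 0 || var(y) == 0)
    stop("constant (zero-variance) input: coherence is undefined")
  if (is.null(grid)) {
    margin <- ceiling(0.6 / (2 / params$voicesPerOctave)) + 1L
    grid <- buildScaleGrid(band$bandLo, band$bandHi, params, fs,
                           marginVoices = margin)
  }
  stopifnot(identical(grid$fs, fs))
  scalesSamp <- grid$scales * fs
  vals <- .wtcCore(as.numeric(x), as.numeric(y), scalesSamp,
                   params$omega0, grid$dj, smooth)
  n <- length(x)
  times <- (seq_len(n) - 1L) / fs
  edge <- pmin(times, (n - 1L) / fs - times)
  coiPeriod <- edge * 2 * pi / (sqrt(2) * params$omega0)
  coherenceMap(vals, grid$periods, times, coiPeriod)
}
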