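# Real-time-ready fNIRS preprocessing: channel pruning, optical density,
# TDDR motion correction with inherent low-pass, modified Beer-Lambert
# conversion, and baseline PCA for shared systemic physiology.

#' Channel pruning by distance, intensity SNR and intensity range
#'
#' A channel site is kept iff its source-detector distance lies within
#' `sdRange`, and for both wavelengths the raw-intensity mean/std exceeds
#' `snrThresh` and the mean intensity lies within `dRange`.
#'
#' @param intensity raw-intensity matrix, rows = channel x wavelength (in
#'   `geometry$rowId` order), columns = samples; strictly positive.
#' @param geometry data.frame with columns `rowId`, `channel`,
#'   `distanceMm`, `wavelengthNm` (one row per intensity row).
#' @param qc a [qcParams()].
#' @return Named logical keep-mask, one entry per channel site.
#' @export
pruneChannels <- function(intensity, geometry, qc = qcParams()) {
  stopifnot(nrow(intensity) == nrow(geometry), all(intensity > 0))
  mu <- rowMeans(intensity)
  snr <- mu / apply(intensity, 1L, sd)
  rowOk <- snr > qc$snrThresh & mu >= qc$dRange[1] & mu <= qc$dRange[2]
  chans <- unique(geometry$channel)
  keep <- vapply(chans, function(ch) {
    rows <- geometry$channel == ch
    all(rowOk[rows]) &&
      all(geometry$distanceMm[rows] >= qc$sdRange[1] &
          geometry$distanceMm[rows] <= qc$sdRange[2])
  }, logical(1))
  names(keep) <- as.character(chans)
  keep
}

#' Group-level channel exclusion
#'
#' A channel is excluded from the whole analysis when it was pruned in at
#' least `minBad` dyads.
#'
#' @param keepMasks list of per-dyad keep-masks from [pruneChannels()]
#'   (identical channel indexing).
#' @param minBad exclusion threshold (default 3 dyads).
#' @return Character vector of globally excluded channel names.
#' @export
groupExcludeChannels <- function(keepMasks, minBad = 3) {
  stopifnot(length(keepMasks) >= 1)
  bad <- Reduce(`+`, lapply(keepMasks, function(m) as.integer(!m)))
  names(bad) <- names(keepMasks[[1]])
  names(bad)[bad >= minBad]
}

#' Raw intensity to optical density
#'
#' `OD(t) = -ln(I(t) / mean(I))` per row; zero-mean in the log domain by
#' construction.
#'
#' @param intensity strictly positive matrix (rows = channel x wavelength)
#'   or vector.
#' @return Optical-density series of the same shape.
#' @export
intensityToOd <- function(intensity) {
  vec <- is.vector(intensity)
  if (vec) intensity <- matrix(intensity, nrow = 1L)
  if (any(intensity <= 0)) stop("intensity must be strictly positive")
  od <- -log(intensity / rowMeans(intensity))
  if (vec) od[1L, ] else od
}

# robust location of the derivative by iteratively reweighted Tukey
# biweight; returns the converged weights and location
tddrWeights <- function(d, tol = 1e-8, maxIter = 50L) {
  mu <- 0
  w <- rep(1, length(d))
  for (i in seq_len(maxIter)) {
    r <- d - mu
    sigma <- 1.4826 * median(abs(r))
    if (sigma == 0) return(list(w = w, mu = mu, converged = TRUE))
    u <- r / (4.685 * sigma)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    muNew <- sum(w * d) / sum(w)
    if (abs(muNew - mu) < tol)
      return(list(w = w, mu = muNew, converged = TRUE))
    mu <- muNew
  }
  warning("TDDR robust location did not converge; using last iterate")
  list(w = w, mu = mu, converged = FALSE)
}

#' Temporal Derivative Distribution Repair motion correction
#'
#' Zero-phase low-pass filters the signal (3rd-order Butterworth applied
#' forward-backward), then robustly reweights its temporal derivative:
#' residuals from an iteratively reweighted robust location get Tukey
#' biweight weights (scale `1.4826 * median |r|`, cutoff `4.685 * sigma`),
#' the weighted residual derivative is re-integrated from the original
#' initial value. Motion spikes and baseline shifts produce derivative
#' outliers and are suppressed; the filtered-out high-frequency content is
#' deliberately not restored.
#'
#' @param od optical-density (or concentration) matrix, rows = series, or
#'   a vector.
#' @param fs sampling rate in Hz (must exceed `2 * lpfCutoff`).
#' @param lpfCutoff low-pass cutoff in Hz (default 0.2, below typical
#'   respiration rates).
#' @param tol convergence tolerance on the robust location.
#' @param maxIter maximum reweighting iterations.
#' @return Corrected series, same shape as `od`.
#' @export
tddrCorrect <- function(od, fs, lpfCutoff = 0.2, tol = 1e-8, maxIter = 50L) {
  stopifnot(fs > 2 * lpfCutoff)
  vec <- is.vector(od)
  if (vec) od <- matrix(od, nrow = 1L)
  bf <- signal::butter(3, lpfCutoff / (fs / 2), type = "low")
  out <- od
  for (r in seq_len(nrow(od))) {
    x <- signal::filtfilt(bf, od[r, ])
    d <- diff(x)
    rw <- tddrWeights(d, tol = tol, maxIter = maxIter)
    dc <- rw$w * (d - rw$mu)
    out[r, ] <- x[1L] + c(0, cumsum(dc))
  }
  if (vec) out[1L, ] else out
}

#' Optical density to hemoglobin concentration changes
#'
#' Solves the 2x2 modified Beer-Lambert system
#' `deltaOD = E * deltaC * d * ppf` per channel and time point, where `E`
#' holds the extinction coefficients of HbO/HbR at the channel's two
#' wavelengths and `d` is the source-detector distance in cm.
#'
#' @param od optical-density matrix, rows = channel x wavelength in
#'   `geometry$rowId` order.
#' @param geometry as in [pruneChannels()].
#' @param mbll an [mbllParams()].
#' @return Concentration-change matrix in mM, rows named
#'   `"<channel>:HbO"` / `"<channel>:HbR"`.
#' @export
odToConc <- function(od, geometry, mbll = mbllParams()) {
  stopifnot(nrow(od) == nrow(geometry))
  chans <- unique(geometry$channel)
  out <- matrix(0, 2L * length(chans), ncol(od))
  rn <- character(2L * length(chans))
  for (i in seq_along(chans)) {
    rows <- which(geometry$channel == chans[i])
    if (length(rows) != 2L)
      stop("exactly two wavelengths per channel site required")
    wl <- as.character(geometry$wavelengthNm[rows])
    E <- t(mbll$extinction[, wl, drop = FALSE])  # rows: wavelengths
    if (abs(det(E)) < 1e-12) stop("singular extinction matrix")
    dCm <- geometry$distanceMm[rows[1]] / 10
    conc <- solve(E, od[rows, , drop = FALSE]) / (dCm * mbll$ppf)
    out[2L * i - 1L, ] <- conc[1L, ]
    out[2L * i, ] <- conc[2L, ]
    rn[2L * i - 1L] <- paste0(chans[i], ":", rownames(mbll$extinction)[1])
    rn[2L * i] <- paste0(chans[i], ":", rownames(mbll$extinction)[2])
  }
  rownames(out) <- rn
  out
}

#' Baseline-PCA removal of shared systemic physiology
#'
#' Estimates the spatial profile of extracerebral systemic noise from a
#' separate baseline segment: the baseline (channels x time) is
#' mean-centered per channel, its leading spatial principal components are
#' computed, and the projection of the investigation data onto those
#' components is subtracted. Exactly
#' `filtered + removed = investigation`.
#'
#' @param investigation channels x time matrix to be cleaned.
#' @param baseline channels x time matrix (same channel set; tens of
#'   seconds or more).
#' @param nComponents number of spatial noise components to remove
#'   (default 1; at most the number of channels).
#' @return List: `filtered`, `removed`, and `components` (channels x
#'   nComponents orthonormal spatial loadings).
#' @export
baselinePcaFilter <- function(investigation, baseline, nComponents = 1L) {
  stopifnot(nrow(investigation) == nrow(baseline))
  if (nComponents > nrow(baseline))
    stop("more components than channels")
  bc <- baseline - rowMeans(baseline)
  U <- svd(bc, nu = nComponents, nv = 0)$u
  removed <- U %*% (t(U) %*% investigation)
  list(filtered = investigation - removed, removed = removed,
       components = U)
}

#' Full preprocessing chain for a raw-intensity dyad recording
#'
#' Runs pruning, optical-density conversion, TDDR motion correction,
#' Beer-Lambert concentration conversion and baseline PCA on both subjects
#' of a raw-intensity recording, returning a concentration recording for
#' one chromophore.
#'
#' @param rec raw-intensity \linkS4class{DyadRecording} (rows = channel x
#'   wavelength in `geometry$rowId` order).
#' @param geometry as in [pruneChannels()].
#' @param baselineWindow `c(start, end)` seconds of the rest segment used
#'   to estimate the systemic spatial profile.
#' @param qc a [qcParams()].
#' @param mbll an [mbllParams()].
#' @param chromophore `"HbO"` or `"HbR"`.
#' @param lpfCutoff TDDR low-pass cutoff in Hz.
#' @param nComponents baseline-PCA components to remove.
#' @return \linkS4class{DyadRecording} of concentration changes (one row
#'   per kept channel) with the keep-mask in `attr(, "keepMask")`.
#' @export
preprocessDyad <- function(rec, geometry, baselineWindow,
                           qc = qcParams(), mbll = mbllParams(),
                           chromophore = c("HbO", "HbR"),
                           lpfCutoff = 0.2, nComponents = 1L) {
  chromophore <- match.arg(chromophore)
  stopifnot(is(rec, "DyadRecording"))
  fs <- rec@fs
  keep <- pruneChannels(rbind(rec@subjectA, rec@subjectB),
                        rbind(geometry, geometry), qc)
  keptRows <- geometry$channel %in% names(keep)[keep]
  geomKept <- geometry[keptRows, , drop = FALSE]
  if (!any(keptRows)) stop("all channels pruned")
  b0 <- floor(baselineWindow[1] * fs) + 1L
  b1 <- floor(baselineWindow[2] * fs)
  oneSubject <- function(intensity) {
    conc <- odToConc(
      tddrCorrect(intensityToOd(intensity[keptRows, , drop = FALSE]),
                  fs, lpfCutoff),
      geomKept, mbll)
    sel <- grepl(paste0(":", chromophore, "$"), rownames(conc))
    chrom <- conc[sel, , drop = FALSE]
    baselinePcaFilter(chrom, chrom[, b0:b1, drop = FALSE],
                      nComponents)$filtered
  }
  out <- dyadRecording(oneSubject(rec@subjectA), oneSubject(rec@subjectB),
                       fs = fs,
                       channelIds = as.character(unique(geomKept$channel)),
                       dyadId = rec@dyadId)
  attr(out, "keepMask") <- keep
  out
}
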