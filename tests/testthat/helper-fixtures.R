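# Shared fixtures and the independent R oracle for the coherence core.

rpsDesign <- function() designSpec()  # 60 s rest, 30 events @ 8 s, 60 s rest

# Brute-force wavelet coherence oracle: plain-R Morlet CWT via mvfft on a
# reflection-extended buffer, explicit truncated-Gaussian time smoothing on
# a circular next-pow2 buffer, fractional boxcar across scales. Mirrors the
# definition, not the package's optimized path.
oracleWtc <- function(x, y, fs, params = morletParams(), band = bandSpec()) {
  n <- length(x)
  margin <- ceiling(0.6 * params$voicesPerOctave / 2) + 1L
  g <- buildScaleGrid(band$bandLo, band$bandHi, params, fs,
                      marginVoices = margin)
  sc <- g$scales * fs
  ext <- floor(n / 2)
  refl <- function(z) c(rev(z[1:ext]), z, rev(z[(n - ext + 1):n]))
  ne <- n + 2L * ext
  npad <- 2^ceiling(log2(ne))
  om <- 2 * pi * (0:(npad - 1)) / npad
  cwt1 <- function(z) {
    zf <- fft(c(refl(z), rep(0, npad - ne)))
    sapply(seq_along(sc), function(j) {
      s <- sc[j]
      psi <- sqrt(2 * pi * s) * pi^-0.25 * exp(-0.5 * (s * om - params$omega0)^2)
      psi[om > pi] <- 0
      w <- fft(zf * psi, inverse = TRUE) / npad
      w[(ext + 1):(ext + n)]
    })
  }
  Wx <- cwt1(x); Wy <- cwt1(y)
  np2 <- 2^ceiling(log2(n))
  smoothT <- function(v, sigma) {   # circular conv on np2 buffer
    kk <- 0:(np2 - 1); kk <- ifelse(kk > np2 / 2, kk - np2, kk)
    kern <- rowSums(sapply(-4:4, function(r)      # periodized Gaussian
      exp(-(kk + r * np2)^2 / (2 * sigma^2))))
    kern <- kern / sum(kern)
    f <- fft(c(v, rep(0, np2 - n))) * fft(kern)
    (fft(f, inverse = TRUE) / np2)[1:n]
  }
  P <- list(xx = sweep(abs(Wx)^2, 2, sc, "/"),
            yy = sweep(abs(Wy)^2, 2, sc, "/"),
            xy = sweep(Wx * Conj(Wy), 2, sc, "/"))
  S <- lapply(P, function(F) sapply(seq_along(sc), function(j)
    smoothT(F[, j], sc[j] / sqrt(2))))
  smoothS <- function(F) {   # integer boxcar, ~0.6 octave span
    w <- max(1, round(0.6 * params$voicesPerOctave))
    lo <- -(w %/% 2)
    ns <- ncol(F)
    out <- F * 0
    for (j in seq_len(ns)) {
      jj <- (j + lo):(j + lo + w - 1)
      jj <- jj[jj >= 1 & jj <= ns]
      out[, j] <- rowMeans(F[, jj, drop = FALSE])
    }
    out
  }
  S <- lapply(S, smoothS)
  r2 <- abs(S$xy)^2 / (Re(S$xx) * Re(S$yy))
  list(values = pmin(pmax(Re(r2), 0), 1), periods = g$periods)
}

# AR(1) surrogate with spectral content in the period band of interest
bandNoise <- function(n, fs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = 0.95), n)) +
    0.3 * sin(2 * pi * (0:(n - 1)) / fs / 8)
}
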