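#' Fisher-z transform
#'
#' `atanh` mapping of a bounded (-1, 1) quantity (here the task-minus-rest
#' coherence difference) to the real line.
#'
#' @param delta value(s) strictly inside (-1, 1).
#' @return `atanh(delta)`.
#' @export
fisherZ <- function(delta) {
  if (any(abs(delta) >= 1))
    stop("fisherZ is defined only on (-1, 1)")
  atanh(delta)
}

#' Random-intercept model for the coherence contrast
#'
#' Fits the Gaussian linear mixed model `deltaZ ~ 1 + (1 | dyadId)` by REML
#' and tests the fixed intercept against zero (the null hypothesis of no
#' task-vs-rest coherence difference) with a Wald t statistic. With one
#' observation per dyad, or when the dyad variance component is estimated
#' singular, the fit falls back to pooled ordinary least squares and is
#' flagged.
#'
#' @param deltas data.frame with columns `dyadId` and `deltaZ` (additional
#'   columns are ignored); at least two dyads.
#' @param dfMethod degrees of freedom for the Wald p: `"groups"`
#'   (`nGroups - 1`, the between-dyad df; default, exact for the balanced
#'   dyad-mean t-test) or `"residual"` (`nObs - 1`).
#' @return A `FitSummary` record: `intercept`, `se`, `p`, `df`, `nObs`,
#'   `nGroups`, `randomInterceptSd`, `pooled` (fallback flag).
#' @export
fitRandomIntercept <- function(deltas, dfMethod = c("groups", "residual")) {
  dfMethod <- match.arg(dfMethod)
  stopifnot(all(c("dyadId", "deltaZ") %in% names(deltas)))
  z <- deltas$deltaZ
  g <- factor(deltas$dyadId)
  nObs <- length(z)
  nGroups <- nlevels(g)
  if (nGroups < 2) stop("at least two dyads required")

  pooled <- FALSE
  ranefSd <- NA_real_
  if (nObs == nGroups) {
    pooled <- TRUE
  } else {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(z ~ 1 + (1 | g),
                 REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore", calc.derivs = FALSE))))
    if (lme4::isSingular(fit, tol = 1e-6)) {
      pooled <- TRUE
    } else {
      co <- summary(fit)$coefficients
      est <- co[1, "Estimate"]
      se <- co[1, "Std. Error"]
      vc <- as.data.frame(lme4::VarCorr(fit))
      ranefSd <- vc$sdcor[vc$grp == "g"]
    }
  }
  if (pooled) {
    est <- mean(z)
    se <- sd(z) / sqrt(nObs)
    ranefSd <- 0
  }
  df <- if (dfMethod == "groups" && !pooled) nGroups - 1L else nObs - 1L
  p <- if (se > 0) 2 * pt(-abs(est / se), df = df) else as.numeric(est == 0)
  recordClass(list(intercept = est, se = se, p = p, df = df,
                   nObs = nObs, nGroups = nGroups,
                   randomInterceptSd = ranefSd, pooled = pooled),
              "FitSummary")
}

#' Average fit summaries across iterations
#'
#' Arithmetic means of intercept, standard error and p across the
#' per-iteration model fits.
#'
#' @param fits list of `FitSummary` records from [fitRandomIntercept()].
#' @return List with `meanIntercept`, `meanSe`, `meanP`, `nIterations`.
#' @export
aggregateIterations <- function(fits) {
  stopifnot(length(fits) >= 1)
  list(
    meanIntercept = mean(vapply(fits, `[[`, numeric(1), "intercept")),
    meanSe = mean(vapply(fits, `[[`, numeric(1), "se")),
    meanP = mean(vapply(fits, `[[`, numeric(1), "p")),
    nIterations = length(fits)
  )
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up false discovery rate control: flags the hypotheses significant
#' at level `q` over the whole family.
#'
#' @param p p-values in [0, 1].
#' @param q FDR level.
#' @return Logical vector of significance flags (downward-closed in sorted
#'   p order).
#' @export
bhFdr <- function(p, q = 0.05) {
  if (!length(p)) return(logical(0))
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH") <= q
}

#' Simulation grid over SNR levels and window modes
#'
#' Reruns the full simulation experiment: for each SNR level, simulates
#' `nIterations` cohorts of `nDyads` dyads, computes the windowed /
#' complete-block / offline task-vs-rest contrasts, fits the
#' random-intercept model per iteration and mode, and averages the fits
#' across iterations.
#'
#' @param snrDb vector of SNR levels in dB.
#' @param design a [designSpec()].
#' @param hrf an [hrfParams()].
#' @param scheme a [windowScheme()].
#' @param band a [bandSpec()].
#' @param params a [morletParams()].
#' @param nDyads,nIterations cohort size per iteration / iteration count.
#' @param seed master seed; each SNR level derives its own child seed.
#' @param dfMethod passed to [fitRandomIntercept()].
#' @return data.frame with one row per SNR x mode: `snrDb`, `mode`,
#'   `meanIntercept`, `meanSe`, `meanP`, `nIterations`.
#' @export
runTable1 <- function(snrDb = c(1.90, 0.03, -2.19, -7.05, -10.15, -12.08),
                      design = designSpec(), hrf = hrfParams(),
                      scheme = windowScheme(), band = bandSpec(),
                      params = morletParams(), nDyads = 25,
                      nIterations = 50, seed = 1L,
                      dfMethod = "groups") {
  layout <- layoutFromDesign(design)
  snrSeeds <- childSeeds(seed, length(snrDb))
  rows <- list()
  for (si in seq_along(snrDb)) {
    cfg <- simConfig(design, hrf, snrDb = snrDb[si], nDyads = nDyads,
                     nIterations = nIterations, seed = snrSeeds[si])
    cohort <- simulateCohort(cfg)
    fitsByMode <- list()
    for (it in seq_along(cohort)) {
      recs <- do.call(rbind, lapply(cohort[[it]], windowWtcForDyad,
                                    layout = layout, scheme = scheme,
                                    band = band, params = params))
      for (mode in unique(recs$mode)) {
        fit <- fitRandomIntercept(recs[recs$mode == mode, , drop = FALSE],
                                  dfMethod = dfMethod)
        fitsByMode[[mode]] <- c(fitsByMode[[mode]], list(fit))
      }
    }
    for (mode in names(fitsByMode)) {
      agg <- aggregateIterations(fitsByMode[[mode]])
      rows[[length(rows) + 1L]] <- data.frame(
        snrDb = snrDb[si], mode = mode,
        meanIntercept = agg$meanIntercept, meanSe = agg$meanSe,
        meanP = agg$meanP, nIterations = agg$nIterations,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-cell significance flags for a channel x mode analysis
#'
#' Applies [bhFdr()] across all cells of one dataset analysis (the FDR
#' family is every channel x window-size cell).
#'
#' @param cells data.frame with at least a `p` column (one row per
#'   channel x mode cell).
#' @param q FDR level.
#' @return `cells` with a logical `qSignificant` column appended.
#' @export
flagCells <- function(cells, q = 0.05) {
  stopifnot("p" %in% names(cells))
  cells$qSignificant <- bhFdr(cells$p, q)
  cells
}
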