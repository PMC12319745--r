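geomFor <- function(nCh, dist = 30) data.frame(
  rowId = paste0("r", seq_len(2 * nCh)),
  channel = rep(seq_len(nCh), each = 2),
  source = rep(seq_len(nCh), each = 2),
  detector = rep(seq_len(nCh), each = 2),
  distanceMm = dist,
  wavelengthNm = rep(c(760, 850), nCh))

test_that("pruning keeps clean channels and drops violators", {
  set.seed(1)
  n <- 500
  mk <- function(mu, sdv) pmax(mu + rnorm(n, 0, sdv), 1e-6)
  geom <- geomFor(4)
  geom$distanceMm[geom$channel == 4] <- 60        # outside SD range
  intens <- rbind(mk(1, 0.05), mk(1, 0.05),       # ch1 clean
                  mk(1, 1 / 1.5), mk(1, 0.05),    # ch2: SNR ~1.5 < 2
                  mk(0.001, 1e-5), mk(1, 0.05),   # ch3: below dRange floor
                  mk(1, 0.05), mk(1, 0.05))       # ch4: bad geometry
  keep <- pruneChannels(intens, geom, qcParams())
  expect_identical(unname(keep), c(TRUE, FALSE, FALSE, FALSE))
  # idempotence: pruning the kept subset changes nothing
  rows <- geom$channel %in% names(keep)[keep]
  keep2 <- pruneChannels(intens[rows, , drop = FALSE], geom[rows, ],
                         qcParams())
  expect_true(all(keep2))
})

test_that("group exclusion needs at least minBad bad dyads", {
  m <- function(...) setNames(c(...), paste0("ch", 1:3))
  masks <- list(m(TRUE, FALSE, TRUE), m(TRUE, FALSE, TRUE),
                m(TRUE, FALSE, FALSE), m(TRUE, TRUE, FALSE))
  expect_identical(groupExcludeChannels(masks), "ch2")   # bad 3 times
  expect_identical(groupExcludeChannels(masks, minBad = 2), c("ch2", "ch3"))
  clean <- replicate(5, m(TRUE, TRUE, TRUE), simplify = FALSE)
  expect_length(groupExcludeChannels(clean), 0)
})

test_that("optical density conversion is the mean-referenced log ratio", {
  expect_equal(intensityToOd(rep(2, 50)), rep(0, 50))
  # one sample at mean * exp(-0.1): OD exactly 0.1 there
  i <- rep(1, 100)
  i[7] <- 99 * exp(-0.1) / (100 - exp(-0.1))   # solves i7 = mean(i) e^-0.1
  odPlain <- intensityToOd(i)
  expect_equal(odPlain[7], 0.1, tolerance = 1e-9)
  expect_error(intensityToOd(c(1, 0, 2)), "positive")
  # round trip
  set.seed(2)
  raw <- matrix(exp(rnorm(200, 0, 0.1)), 2)
  od2 <- intensityToOd(raw)
  backI <- rowMeans(raw) * exp(-od2)
  expect_equal(backI, raw, tolerance = 1e-12)
})

test_that("TDDR suppresses spikes and baseline shifts, passes slow signal", {
  fs <- 7.81
  fx <- makePreprocessingFixture(
    nChannels = 2,
    artifactSpec = list(spikeTimes = 120, spikeAmp = 0.15, spikeWidth = 1.3,
                        stepTimes = 220, stepAmp = 0.12,
                        systemicAmp = 0, noiseSd = 5e-4),
    seed = 6)
  od <- intensityToOd(subjectA(fx$recording))
  cor1 <- tddrCorrect(od, fs)
  clean <- fx$truth$odCleanA
  spikeIdx <- floor(120 * fs) + seq_len(round(1.3 * fs))
  refIdx <- floor(110 * fs) + seq_len(50)      # nearby artifact-free stretch
  spikeAmp <- function(m) {
    r <- (m - clean)[1, ]
    max(r[spikeIdx]) - mean(r[refIdx])         # height above local level
  }
  expect_gt(spikeAmp(od), 0.12)                  # present before
  expect_lt(spikeAmp(cor1), 0.2 * spikeAmp(od))  # > 80 % reduction
  stepH <- function(m) {
    i <- floor(220 * fs)
    abs(mean(m[1, (i + 20):(i + 120)]) - mean(m[1, (i - 120):(i - 20)]) -
        (mean(clean[1, (i + 20):(i + 120)]) - mean(clean[1, (i - 120):(i - 20)])))
  }
  expect_gt(stepH(od), 0.1)
  expect_lt(stepH(cor1), 0.2 * stepH(od))

  # artifact-free slow oscillation: near passthrough (the robust
  # reweighting deterministically shrinks a pure sinusoid by ~6-9 %,
  # plus zero-phase filter transients at the ends)
  t <- (0:3000) / fs
  sine <- 0.05 * sin(2 * pi * 0.05 * t)
  out <- tddrCorrect(sine, fs)
  expect_lt(sqrt(mean((out - sine)^2)) / sqrt(mean(sine^2)), 0.12)

  # in-band content preserved: coherence with the input > 0.9 in 6-14 s
  x <- 0.02 * sin(2 * pi * t / 10) + 0.01 * sin(2 * pi * t / 7) +
    0.005 * sin(2 * pi * t / 13 + 1)
  xc <- tddrCorrect(x, fs)
  m <- waveletCoherence(x, xc, fs)
  expect_gt(mean(coherenceValues(m)[coiMask(m)]), 0.9)
})

test_that("Beer-Lambert inversion recovers known concentrations", {
  geom <- geomFor(2)
  mb <- mbllParams()
  set.seed(3)
  n <- 80
  conc <- matrix(rnorm(2 * 2 * n, 0, 1e-3), 4)     # ch x chromo stacked
  E <- t(mb$extinction[, c("760", "850")])
  od <- rbind(E %*% conc[1:2, ], E %*% conc[3:4, ]) * 3 * 6  # d=3cm, ppf 6
  rec <- odToConc(od, geom, mb)
  expect_equal(unname(rec), unname(conc), tolerance = 1e-12)
  expect_equal(rownames(rec), c("1:HbO", "1:HbR", "2:HbO", "2:HbR"))
  # zero OD and ppf linearity
  expect_true(all(odToConc(od * 0, geom, mb) == 0))
  half <- odToConc(od, geom, mbllParams(ppf = 12))
  expect_equal(unname(half), unname(conc) / 2, tolerance = 1e-12)
  badE <- matrix(c(1, 2, 2, 4), 2, dimnames = list(c("HbO", "HbR"),
                                                   c("760", "850")))
  expect_error(odToConc(od, geom, mbllParams(extinction = badE)),
               "singular")
})

test_that("baseline PCA removes the shared systemic subspace and no more", {
  set.seed(4)
  nCh <- 5; n <- 800
  v <- rnorm(nCh); v <- v / sqrt(sum(v^2))
  sysB <- sin(2 * pi * (1:n) / 80)
  base <- v %*% t(sysB) + matrix(rnorm(nCh * n, 0, 0.01), nCh)
  # investigation data orthogonal to the loading: unchanged
  w <- rnorm(nCh); w <- w - sum(w * v) * v; w <- w / sqrt(sum(w^2))
  orth <- w %*% t(rnorm(n))
  outO <- baselinePcaFilter(orth, base)
  expect_equal(outO$filtered, orth, tolerance = 0.02)
  # pure injected systemic: residual variance < 10 %
  inv <- v %*% t(sin(2 * pi * (1:n) / 77 + 1))
  outS <- baselinePcaFilter(inv, base)
  expect_lt(sum(outS$filtered^2) / sum(inv^2), 0.1)
  # exact decomposition and completeness
  mixed <- inv + orth
  outM <- baselinePcaFilter(mixed, base)
  expect_equal(outM$filtered + outM$removed, mixed, tolerance = 1e-12)
  outAll <- baselinePcaFilter(mixed, base, nComponents = nCh)
  expect_lt(sum(outAll$filtered^2) / sum(mixed^2), 1e-20)
  expect_error(baselinePcaFilter(mixed, base, nComponents = 6), "components")
})

test_that("full chain improves the task contrast on artifact fixtures", {
  fs <- 7.81
  band <- bandSpec()
  lay <- phaseLayout()
  sch <- windowScheme(lengths = 50, completeBlock = FALSE, offline = FALSE)
  deltas <- t(sapply(1:20, function(i) {
    fx <- makePreprocessingFixture(
      nChannels = 4,
      artifactSpec = list(spikeTimes = c(90, 170, 250), spikeAmp = 0.12,
                          stepTimes = 130, stepAmp = 0.08,
                          systemicAmp = 0.02, noiseSd = 2e-3),
      seed = 100 + i)
    rec <- fx$recording
    # uncorrected: raw OD of the first channel pair
    odA <- intensityToOd(subjectA(rec)); odB <- intensityToOd(subjectB(rec))
    raw <- dyadRecording(odA[1, ], odB[1, ], fs)
    dRaw <- mean(windowWtcForDyad(raw, lay, sch, band)$deltaZ)
    # corrected: full chain, same channel, HbO
    pp <- preprocessDyad(rec, fx$geometry, baselineWindow = c(300, 360))
    cor <- dyadRecording(subjectA(pp)[1, ], subjectB(pp)[1, ], fs)
    dCor <- mean(windowWtcForDyad(cor, lay, sch, band)$deltaZ)
    c(raw = dRaw, cor = dCor)
  }))
  expect_gt(mean(deltas[, "cor"] - deltas[, "raw"]), 0)
})
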