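fakeMap <- function(vals, periodsS, fs = 7.81) {
  n <- nrow(vals)
  times <- (seq_len(n) - 1) / fs
  edge <- pmin(times, max(times) - times)
  hyperibs:::coherenceMap(vals, periodsS, times,
                          edge * 2 * pi / (sqrt(2) * 6))
}

test_that("band mean censors the Mayer band and keeps endpoints", {
  p <- c(6, 7, 8, 9, 9.5, 10.5, 11, 12, 14, 15)
  m <- fakeMap(matrix(0.4, 20, 10), p)
  expect_equal(censoredBandMean(m), rep(0.4, 20))
  # value 1 only inside the censored interior: mean must ignore it
  v <- matrix(0, 20, 10); v[, p > 9 & p < 11] <- 1
  expect_equal(censoredBandMean(fakeMap(v, p)), rep(0, 20))
  # distinct per-period constants: hand-computed average of included set
  v2 <- matrix(rep(seq(0.1, 1, by = 0.1), each = 20), 20, 10)
  incl <- (p >= 6 & p <= 9) | (p >= 11 & p <= 14)
  expect_equal(censoredBandMean(fakeMap(v2, p)),
               rep(mean(seq(0.1, 1, 0.1)[incl]), 20))
  expect_error(censoredBandMean(fakeMap(matrix(1, 5, 2), c(20, 30))),
               "band")
})

test_that("task windows are planned maximally with offsets", {
  w <- planTaskWindows(60, 300, 50, 8)
  expect_equal(w[, "start"], c(68, 126, 184, 242))
  expect_equal(w[, "end"] - w[, "start"], rep(50, 4))
  expect_equal(nrow(planTaskWindows(60, 300, 100, 8)), 2)
  expect_equal(planTaskWindows(60, 300, 100, 8)[, "start"], c(68, 176))
  expect_equal(nrow(planTaskWindows(0, 240, 250, 8)), 0)
  # disjointness with at least the offset between consecutive windows
  for (len in c(50, 60, 70, 80, 90, 100)) {
    w <- planTaskWindows(60, 300, len, 8)
    if (nrow(w) > 1)
      expect_true(all(w[-1, "start"] - w[-nrow(w), "end"] >= 8))
    expect_true(all(w[, "end"] <= 300 & w[, "start"] >= 68))
  }
})

test_that("trimmed window mean drops the COI-contaminated edges", {
  fs <- 7.81
  s <- rep(0.7, 3000)
  expect_equal(trimmedWindowMean(s, fs, c(10, 70), 18.9), 0.7)
  # step series: 0 inside the trim zones, 1 in the core
  tr <- ceiling(18.9 * fs)
  s2 <- numeric(floor(50 * fs))
  s2[(tr + 1):(floor(50 * fs) - tr)] <- 1
  expect_equal(trimmedWindowMean(s2, fs, c(0, 50), 18.9), 1)
  # a 50 s window at 7.81 Hz keeps a core of roughly 12 s (94-97 samples)
  core <- floor(50 * fs) - 2 * tr
  expect_gte(core, 94); expect_lte(core, 97)
  expect_error(trimmedWindowMean(s, fs, c(0, 30), 18.9), "too short")
})

test_that("per-dyad contrast is near zero for identical or exchangeable subjects", {
  fs <- 7.81
  x <- bandNoise(2812, fs, seed = 21)
  dy <- dyadRecording(x, x, fs = fs, dyadId = "twin")
  recs <- windowWtcForDyad(dy, phaseLayout(), windowScheme(lengths = 50))
  expect_equal(nrow(recs), 4 + 1 + 1)        # 4 windows + complete + offline
  expect_true(all(recs$wtcTask > 0.99))
  expect_true(all(recs$wtcRest > 0.99))
  expect_true(all(abs(recs$deltaZ) < 0.02))
  expect_true(all(recs$mode %in% c("50s", "complete", "offline")))
})

test_that("windowed mode uses only samples inside the window", {
  fs <- 7.81
  set.seed(31)
  a <- rnorm(2812); b <- rnorm(2812)
  sch <- windowScheme(lengths = 50, completeBlock = FALSE, offline = FALSE)
  base <- windowWtcForDyad(dyadRecording(a, b, fs), phaseLayout(), sch)
  # perturb all samples outside the second window [126, 176)
  i0 <- floor(126 * fs) + 1L; i1 <- floor(176 * fs)
  a2 <- rnorm(2812) * 5; a2[i0:i1] <- a[i0:i1]
  b2 <- rnorm(2812) * 5; b2[i0:i1] <- b[i0:i1]
  pert <- windowWtcForDyad(dyadRecording(a2, b2, fs), phaseLayout(), sch)
  expect_equal(pert$wtcTask[pert$windowIndex == 2],
               base$wtcTask[base$windowIndex == 2], tolerance = 1e-12)
})

test_that("windowed and offline modes agree in expectation on stationary signals", {
  fs <- 7.81
  set.seed(41)
  diffs <- replicate(50, {
    s <- as.numeric(arima.sim(list(ar = 0.95), 2812))
    a <- s + rnorm(2812, 0, 2)
    b <- s + rnorm(2812, 0, 2)
    r <- windowWtcForDyad(dyadRecording(a, b, fs), phaseLayout(),
                          windowScheme(lengths = 50))
    mean(r$wtcTask[r$mode == "50s"]) - r$wtcTask[r$mode == "offline"]
  })
  expect_gt(t.test(diffs)$p.value, 0.05)
})

test_that("deltaZ is finite for means inside the unit interval", {
  fs <- 7.81
  set.seed(51)
  for (i in 1:3) {
    dy <- dyadRecording(rnorm(2812), rnorm(2812), fs)
    r <- windowWtcForDyad(dy, phaseLayout(), windowScheme(lengths = c(50, 80)))
    expect_true(all(is.finite(r$deltaZ)))
    expect_true(all(r$wtcTask >= 0 & r$wtcTask <= 1))
    expect_true(all(r$wtcRest >= 0 & r$wtcRest <= 1))
  }
})
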