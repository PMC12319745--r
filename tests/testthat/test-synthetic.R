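test_that("event vector follows the block design", {
  d <- rpsDesign()
  ev <- buildEventVector(d)
  expect_length(ev, 2812)          # round(360 * 7.81)
  onsets <- which(ev == 1)
  expect_length(onsets, 30)
  # onset times 60, 68, ..., 292 s mapped by flooring
  expect_equal(onsets, floor((60 + 8 * (0:29)) * d$fs) + 1L)
  expect_true(all(ev[-onsets] == 0))

  expect_true(all(buildEventVector(designSpec(nEvents = 0)) == 0))
  expect_error(buildEventVector(designSpec(fs = -1)), "fs")
})

test_that("HRF kernel is a peak-normalized double gamma", {
  k10 <- hrfKernel(hrfParams(), fs = 10)
  expect_length(k10, 320)
  expect_equal(max(k10), 1)
  # peak between 4 and 7 s (dense-grid oracle for the default parameters)
  tDense <- seq(0, 32, by = 1e-3)
  hDense <- dgamma(tDense, 6, 1) - dgamma(tDense, 16, 1) / 6
  peakT <- tDense[which.max(hDense)]
  expect_gt(peakT, 4); expect_lt(peakT, 7)
  expect_equal((which.max(k10) - 1) / 10, peakT, tolerance = 0.05)
  # infinite peak:undershoot ratio leaves a single gamma density
  kInf <- hrfKernel(hrfParams(peakUndershootRatio = Inf), fs = 10)
  t <- (0:319) / 10
  expect_equal(kInf, dgamma(t, 6, 1) / max(dgamma(t, 6, 1)), tolerance = 1e-12)
})

test_that("clean signal is causal and decays after the last event", {
  d <- rpsDesign()
  y <- simulateCleanSignal(d)
  expect_length(y, 2812)
  expect_true(all(y[seq_len(floor(60 * d$fs))] == 0))  # zero before rest end
  # single event: signal is the kernel shifted to the onset
  d1 <- designSpec(nEvents = 1)
  y1 <- simulateCleanSignal(d1)
  on <- floor(60 * d1$fs) + 1L
  k <- hrfKernel(hrfParams(), d1$fs)
  expect_equal(y1[on:(on + length(k) - 1L)], k, tolerance = 1e-10)
  # last event at 292 s + 32 s kernel: final ~16 s of the recording flat
  tailIdx <- (floor(344 * d$fs) + 1L):length(y)
  expect_lt(max(abs(y[tailIdx])), 1e-12)
})

test_that("noise is calibrated to the requested SNR", {
  d <- rpsDesign()
  clean <- simulateCleanSignal(d)
  # snr 0 dB: noise sd equals clean sd
  set.seed(1)
  reps <- replicate(100, {
    eps <- addNoiseAtSnr(clean, 0) - clean
    c(sd(eps), 10 * log10(var(clean) / var(eps)))
  })
  expect_equal(mean(reps[1, ]), sd(clean), tolerance = 0.01)
  expect_lt(abs(mean(reps[2, ]) - 0), 0.1)   # mean realized SNR within 0.1 dB
  # at the lowest study level too
  set.seed(2)
  real <- replicate(100, {
    eps <- addNoiseAtSnr(clean, -10.15) - clean
    10 * log10(var(clean) / var(eps))
  })
  expect_lt(abs(mean(real) + 10.15), 0.1)
  expect_identical(addNoiseAtSnr(clean, Inf), clean)
  expect_error(addNoiseAtSnr(rep(1, 100), 0), "variance")
})

test_that("cohorts are deterministic with shared activation and independent noise", {
  cfg <- simConfig(design = rpsDesign(), snrDb = 0.03, nDyads = 3,
                   nIterations = 2, seed = 11)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_length(c1, 2)
  expect_length(c1[[1]], 3)
  expect_identical(c1, c2)                       # bit-identical given seed
  lens <- unlist(lapply(c1, function(it) vapply(it, nSamples, 1L)))
  expect_true(all(lens == 2812))
  # both members share the clean signal; their noises are independent
  clean <- simulateCleanSignal(rpsDesign())
  nA <- subjectA(c1[[1]][[1]])[1, ] - clean
  nB <- subjectB(c1[[1]][[1]])[1, ] - clean
  nA2 <- subjectA(c1[[1]][[2]])[1, ] - clean
  expect_lt(abs(cor(nA, nB)), 0.06)
  expect_lt(abs(cor(nA, nA2)), 0.06)
  # null dyads: pure unit-variance noise
  cN <- simulateCohort(simConfig(snrDb = -Inf, nDyads = 2, nIterations = 1,
                                 seed = 5))
  expect_equal(sd(subjectA(cN[[1]][[1]])[1, ]), 1, tolerance = 0.05)
})

test_that("preprocessing fixture carries its ground truth", {
  # no artifacts, no systemic: OD reconstruction equals task + noise
  fx0 <- makePreprocessingFixture(
    nChannels = 3, artifactSpec = list(systemicAmp = 0), seed = 3)
  odA <- -log(subjectA(fx0$recording))          # baseline intensity is 1
  expect_equal(odA, fx0$truth$odCleanA, tolerance = 1e-12)

  fx <- makePreprocessingFixture(
    nChannels = 4,
    artifactSpec = list(spikeTimes = c(100, 200), stepTimes = 150,
                        systemicAmp = 0.02, noiseSd = 1e-4),
    seed = 4)
  expect_equal(fx$truth$spikeTimes, c(100, 200))
  expect_equal(fx$truth$stepTimes, 150)
  # first spatial PC of rest-phase OD aligns with the injected loading
  od <- -log(subjectA(fx$recording))
  rest <- od[, 1:floor(60 * 7.81)]
  chan <- (rest[seq(1, 8, by = 2), ] + rest[seq(2, 8, by = 2), ]) / 2
  u1 <- svd(chan - rowMeans(chan))$u[, 1]
  expect_gt(abs(sum(u1 * fx$truth$systemicLoading)), 0.95)
})
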