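# hyperibs

Short-window wavelet transform coherence (WTC) for fNIRS hyperscanning.

## What this package is for

Interbrain synchrony (IBS) — the temporal coupling of two interacting
people's brain signals — is usually measured in fNIRS hyperscanning with
wavelet transform coherence, computed offline over whole recordings. A
neurofeedback system built on IBS ("hyperfeedback") instead needs the
metric from short windows of data available in (pseudo) real time.
`hyperibs` implements that windowed pipeline for researchers evaluating or
building such systems:

* **Coherence core** — analytic Morlet CWT (ω₀ = 6, 14 voices/octave),
  smoothed squared coherence
  `|S(Wx·conj(Wy)/s)|² / (S(|Wx|²/s)·S(|Wy|²/s))` with Gaussian time
  smoothing (std s/√2) and a ~0.6-octave scale boxcar, toolbox-style
  reflection/circular boundary handling, and the closed-form cone of
  influence `COI(p) = √2·ω₀·p/(2π)` (18.90 s at p = 14 s).
* **Windowed analysis** — band average over periods 6–9 s and 11–14 s
  (9–11 s censored against Mayer-wave artifacts), non-overlapping task
  windows of 50–100 s with 8 s offsets, COI trimming of 18.90 s per window
  end, rest-phase baseline, and three modes: per-window ("windowed"),
  whole-task-block ("complete"), and conventional full-time-course
  ("offline"). The contrast is `ΔWTC = WTC_task_window − WTC_rest`,
  Fisher-z transformed.
* **Dyad simulator** — event-related design (60 s rest, 30 events at 8 s
  intervals, 60 s rest, 7.81 Hz), canonical double-gamma HRF, shared
  activation per dyad with independent Gaussian noise at calibrated SNR
  (dB, whole-course power ratio).
* **Preprocessing** — channel pruning, group-level channel exclusion,
  optical density, TDDR motion correction with an inherent 0.2 Hz
  low-pass, modified Beer–Lambert conversion (ppf 6), and baseline PCA for
  shared systemic physiology — each step real-time-ready.
* **Statistics** — per-iteration Gaussian mixed model
  `ΔWTC ~ 1 + (1|dyadID)` (lme4, REML, Wald test), aggregation across
  iterations, Benjamini–Hochberg FDR (q < 0.05) across channel × window
  cells.

## Worked example

Simulate a cohort at a high noise level (SNR −7.05 dB), run the windowed
analysis with 50 s windows, and fit the group model for one iteration:

```r
library(hyperibs)

cfg <- simConfig(snrDb = -7.05, nDyads = 25, nIterations = 2, seed = 7)
cohort <- simulateCohort(cfg)
recs <- do.call(rbind, lapply(cohort[[1]], windowWtcForDyad,
                              layout = layoutFromDesign(cfg$design),
                              scheme = windowScheme(lengths = 50)))
head(recs[, c("dyadId", "mode", "windowIndex", "wtcTask", "wtcRest", "deltaZ")], 4)
#>   dyadId mode windowIndex   wtcTask   wtcRest     deltaZ
#> 1 dyad01  50s           1 0.6002897 0.4278839 0.17414513
#> 2 dyad01  50s           2 0.4535027 0.4278839 0.02562437
#> 3 dyad01  50s           3 0.6313582 0.4278839 0.20635427
#> 4 dyad01  50s           4 0.5854831 0.4278839 0.15892375

fit <- fitRandomIntercept(recs[recs$mode == "50s", ])
unlist(fit[c("intercept", "se", "p", "nObs", "nGroups")])
#>    intercept           se            p         nObs      nGroups
#> 1.779560e-01 2.910529e-02 2.574715e-06 1.000000e+02 2.500000e+01
```

Reading the output: each row is one 50 s task window of one dyad.
`wtcTask` is the Mayer-censored band coherence averaged over the window's
COI-trimmed core; `wtcRest` the same for that dyad's rest baseline;
`deltaZ` their Fisher-z difference. The mixed-model intercept (0.178 ± 0.029
Fisher-z units, p ≈ 2.6 × 10⁻⁶ across 100 windows from 25 dyads) is the
group-level task-versus-rest synchrony contrast: even at this noise level a
50 s window carries a clearly detectable IBS signal, while the rest-phase
coherence (~0.43) reflects the estimator's noise floor, not true coupling.

`runTable1()` repeats this over iterations, SNR levels and all window
modes; `cliMain()` / `inst/cli/hyperibs` expose `simulate`, `ibs` and
`table1` stages on the command line, reading and writing plain delimited
recordings (`readDyadRecording()` documents the format).

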