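---
title: "Short-window wavelet coherence for fNIRS hyperscanning: methods and design"
author: "hyperibs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-window wavelet coherence for fNIRS hyperscanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperibs)
```

## The problem

Interbrain synchrony (IBS) between two interacting people is most commonly
quantified by wavelet transform coherence (WTC) of fNIRS signals recorded
simultaneously from both partners. Conventional analyses transform the whole
recording at once and average coherence over long task blocks. A
neurofeedback system that feeds IBS back to the participants cannot do that:
it only ever has the data up to "now", and must produce a meaningful number
from a short window. `hyperibs` implements that short-window, pseudo-real-time
WTC pipeline end to end — simulation of dyads, preprocessing, windowed
coherence, and group statistics — so that the feasibility question ("is the
task-versus-rest IBS contrast still detectable in windows of about a
minute?") can be answered by simulation, and so that real dyadic recordings
can be pushed through the identical analysis.

## The coherence estimator

Both signals are transformed with an analytic Morlet wavelet (center
frequency $\omega_0 = 6$) on a logarithmic period grid with 14 voices per
octave. Periods $p$ and wavelet scales $s$ are related by
$p = 2\pi s/\omega_0$; under this convention the cone of influence (COI) —
the per-end stretch of a segment in which edge effects are non-negligible —
has the closed form

$$ \mathrm{COI}(p) = \frac{\sqrt{2}\,\omega_0}{2\pi}\, p, $$

which is 18.90 s at the band edge $p = 14$ s (`coiSeconds(14)`). Squared
coherence is the smoothed cross-spectrum normalized by the smoothed
auto-spectra,

$$ R^2(t, s) =
  \frac{\bigl|S\!\left(W_x W_y^{*}/s\right)\bigr|^2}
       {S\!\left(|W_x|^2/s\right)\, S\!\left(|W_y|^2/s\right)}, $$

with a two-stage smoothing operator $S$: per scale, a Gaussian in time with
standard deviation $s/\sqrt{2}$ (the squared Morlet envelope), then a boxcar
across scales spanning about 0.6 octaves. Without $S$, $R^2 \equiv 1$ — the
textbook degeneracy — and a test guards that smoothing is active.

Boundary handling follows the conventions of the widely used
wavelet-coherence toolboxes, and it matters for short windows: each segment
is reflection-extended by half its length on either side before the
transform, and the smoothing convolutions run on a next-power-of-two FFT
buffer, which makes them circular when the segment is short. We found in
development that these boundary conventions — not the smoothing spans —
control how the estimator behaves as windows shrink: with plain zero
padding, the estimator's small-sample bias depends strongly on segment
length, the window modes spread apart, and the low-SNR contrast roughly
doubles. With the reflection/circular conventions all window modes agree to
within a few hundredths across the whole noise ladder, which is the
behaviour the reference simulation grid exhibits. Absolute coherence levels
remain implementation-dependent at the level of a few hundredths, because
published pipelines do not fully specify their smoothing; the package
freezes the recipe above and documents it.

## Windowing

The band of interest is 6–14 s, with periods between 9 and 11 s censored
before averaging: Mayer waves (systemic ~0.1 Hz blood-pressure oscillations)
can synchronize between subjects for reasons that have nothing to do with
the brain, so the grid points they would contaminate are excluded and the
band mean runs over 6–9 s and 11–14 s (`censoredBandMean()`).

Task windows of 50–100 s are placed left to right with an 8 s offset before
the first window and between windows (hemodynamic delay, independence), as
many as fit (`planTaskWindows()`; a 240 s task phase holds 4/3/3/2/2/2
windows for lengths 50/60/70/80/90/100 s). Each excised window is
transformed on its own — exactly what a real-time system can do — its band
coherence series is trimmed by the COI of the largest band period
(18.90 s per end, rounded up to whole samples) and averaged. The rest-phase
baseline is processed identically. Three modes are compared
(`windowWtcForDyad()`):

* **windowed** — each task window excised and transformed alone;
* **complete** — the whole task phase excised and transformed as one block;
* **offline** — the conventional analysis: one transform of the full
  recording, segment means taken afterwards.

The per-window contrast is Fisher-z transformed,
$\Delta = \operatorname{atanh}(\overline{\mathrm{WTC}}_{task} -
\overline{\mathrm{WTC}}_{rest})$, since the difference is bounded in
$(-1, 1)$. The 50 s minimum window is not arbitrary: two COI trims of
18.90 s leave a ~12 s core, so anything shorter has no usable interior.

## The dyad simulator

`simulateCohort()` generates cohorts matching a timed dyadic-game design:
a 60 s rest, 30 task events 8 s apart (240 s task phase), a closing 60 s
rest, at 7.81 Hz. Events are unit impulses convolved with the canonical
double-gamma hemodynamic response (peak 6 s, undershoot 16 s, unit
dispersions, 1:6 ratio, 32 s kernel, peak-normalized). Both members of a
dyad share this clean activation — the synchrony source — and receive
independent Gaussian noise calibrated so that
$10\log_{10}(\mathrm{var(clean)}/\sigma^2)$ equals the requested SNR, with
the variance taken over the entire time course including rests (the only
unambiguous convention when the full course is modelled). The study grid
uses 25 dyads per iteration, 50 iterations, at SNR levels from 1.90 dB down
to −12.08 dB. `snrDb = -Inf` produces pure-noise null dyads used for size
calibration. One master seed drives deterministic per-iteration, per-dyad
child seeds, so cohorts are bit-reproducible.

What the simulator does *not* emulate: physiological (colored, non-Gaussian)
noise, motion artifacts in the coherence-analysis path, inter-subject timing
jitter, or multi-block designs. Passing simulation tests therefore show that
the pipeline recovers a known, idealized synchrony structure at realistic
noise levels — not that real recordings will behave as cleanly. The artifact
fixture (`makePreprocessingFixture()`) addresses the preprocessing chain
separately: it injects spikes, baseline shifts, and a spatially structured
~0.1 Hz systemic wave into two-wavelength raw intensities with full ground
truth.

## Preprocessing chain

The chain is "real-time-ready" in the sense that every step can operate on a
buffered block: channel pruning by source–detector distance (20–45 mm),
raw-intensity SNR (mean/SD > 2) and intensity range; group-level exclusion
of channels bad in ≥ 3 dyads; optical-density conversion
$\mathrm{OD} = -\ln(I/\bar I)$; TDDR motion correction; modified
Beer–Lambert conversion with a partial pathlength factor of 6; and baseline
PCA against a separate rest segment to remove the leading spatial component
of shared systemic physiology.

TDDR details: a 3rd-order Butterworth low-pass at 0.2 Hz (forward–backward,
zero phase; the cutoff removes respiration-band content) feeds a robust
reweighting of the temporal derivative — iteratively reweighted location
with Tukey biweight weights, scale $1.4826\,\mathrm{median}|r|$, cutoff
$4.685\sigma$, tolerance $10^{-8}$, ≤ 50 iterations — and the weighted
residual derivative is re-integrated. The filtered-out high frequencies are
deliberately not added back. Two numerical notes: derivative outliers
(spikes, steps) are suppressed by > 80 % on fixtures, and the Tukey weights
deterministically shrink even a clean sinusoid by roughly 6–9 % in
amplitude — a property of the algorithm itself, which leaves band coherence
(amplitude-invariant) essentially untouched.

The extinction coefficients compiled into `extinctionTable()` (695/760/830/
850 nm, cm⁻¹ mM⁻¹) follow the standard tabulated hemoglobin spectra. The
baseline-PCA segment defaults to one rest minute, selectable per design.

## Statistics

Per iteration, window mode and channel, the Fisher-z contrasts are fitted
with the Gaussian mixed model `deltaZ ~ 1 + (1 | dyadId)` (REML, `lme4`),
and the fixed intercept is tested against zero by a Wald t statistic. The
degrees of freedom default to `nGroups - 1` (between-dyad df): for balanced
designs this makes the test numerically equivalent to a one-sample t-test on
per-dyad means, which is the behaviour a reviewer can verify by hand; the
residual-df alternative is available via `dfMethod = "residual"` but is
anti-conservative for clustered windows. With one observation per dyad, or a
singular dyad variance, the fit falls back to pooled OLS and is flagged.
Aggregation across iterations is the arithmetic mean of intercept, standard
error, and p. Multiple testing across channel × window-size cells uses
Benjamini–Hochberg FDR at q < 0.05 (`bhFdr()`, `flagCells()`).

## Problem sizes and determinism

The packaged test suite runs the full simulation grid at 25 dyads × 10
iterations per SNR level (the grid's cell estimates then carry a standard
error of about 0.01, comfortably inside the ±0.06 comparison band) and the
null-calibration study at 1000 iterations; `scripts/acceptance.R` uses the
full 50 iterations per cell. All random draws descend from explicit seeds;
rerunning any driver with the same seed reproduces its output bit for bit.

## Known limitations

* Absolute coherence levels depend on the smoothing recipe at the level of
  a few hundredths; comparisons across implementations should use the same
  estimator throughout, as the pipeline does internally.
* The lowest-SNR regime sits at the edge of detectability, and the exact
  point where the contrast loses nominal significance is sensitive to those
  estimator constants; the package's simulated contrast at −12.08 dB runs
  slightly above the reference grid and remains (weakly) significant where
  the reference loses significance.
* The delimited text format is the only on-disk format; HDF5-based
  containers are not supported in this build.
* Homologous-channel pairing only; cross-channel coherence matrices are out
  of scope.
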