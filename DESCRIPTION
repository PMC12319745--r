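Package: hyperibs
Title: Short-Window Wavelet Transform Coherence for fNIRS Hyperscanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing interbrain synchrony (IBS) between two
    interacting people from dyadic fNIRS recordings using wavelet transform
    coherence (WTC) computed in short, pseudo-real-time windows. Provides a
    Morlet continuous wavelet transform and smoothed wavelet coherence with
    cone-of-influence handling, period-band averaging with Mayer-wave
    censoring, baseline/task window planning with COI trimming, a
    real-time-ready fNIRS preprocessing chain (channel pruning, optical
    density conversion, TDDR motion correction, modified Beer-Lambert
    conversion, baseline PCA), a dyad simulator with hemodynamic event
    designs and calibrated Gaussian noise, and random-intercept mixed-model
    statistics with FDR control for the task-versus-rest coherence contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
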