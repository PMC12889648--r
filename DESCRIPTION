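Package: popglm
Title: Population-Level Point-Process GLMs for Cross-Population Spike-Train Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits point-process generalized linear models directly to pooled
    population spike trains in order to estimate directed coupling between
    neural populations. The model combines a B-spline baseline template with
    per-trial piecewise-linear time warping and trial gains, raised-cosine
    self-history and coupling filters, and a nonlinear damping term on a
    smoothed recent-spike count that stabilises forward simulation of pooled
    trains. Includes an exponential integrate-and-fire network simulator with
    log-normal synaptic weights for generating benchmark datasets,
    likelihood-ratio and permutation inference (single-neuron GLM baseline
    with Fisher aggregation, reduced-rank regression baseline, excursion test
    for comparing coupling filters across behavioural conditions), and a
    power/ROC experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    splines,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
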