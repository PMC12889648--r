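# popglm

Population-level point-process GLMs for estimating directed coupling
between pooled neural-population spike trains.

## The problem

Classical point-process GLMs model each neuron's spiking as a function of
the past activity of every other neuron, so the number of coupling
parameters grows quadratically with population size and the per-filter
estimates become noisy.  When the neurons in an area share a common firing
pattern, the interactions of interest live at the *population* level.
`popglm` pools the spike times of a group of similarly tuned neurons into
one population spike train per area (1-ms bins; counts above 1 are kept as
Poisson counts) and models the pooled train's log intensity directly:

    log rate(t)  =  warped baseline template
                  + trial gain
                  + self-history filter * own train
                  + f_damp(Lambda(t))
                  + sum over sources of coupling filter * source train

The per-trial piecewise-linear time warp and gain absorb trial-to-trial
variation in response timing and amplitude (which otherwise masquerades as
coupling), and the nonlinear damping term on the smoothed recent-spike
count `Lambda` restores the stabilising refractory feedback that pooling
destroys, so fitted models can be simulated forward without runaway rates.
The coupling filter `g(d)` is the change in target log rate `d` ms after a
source-population spike.

The package is aimed at systems neuroscientists analysing trial-structured
multi-area recordings (e.g. Neuropixels data with drifting-grating trials)
and at methodologists benchmarking population-coupling estimators.

## What's inside

* `fit_popglm()`, `popglm_control()`, `simulate_popglm()`,
  `component_contributions()`, `filter_curve()` — model fitting (IRLS with
  profiled trial gains, alternating with a per-trial warp grid search),
  forward simulation with instability reporting, per-term decompositions.
* `build_warp()`, `warp_evaluate()`, `warp_inverse()`,
  `detect_template_peaks()`, `estimate_trial_peaks()` — the six-landmark
  time-warping machinery.
* `simulate_eif_network()`, `calibrate_noise()`, `sample_weights()`,
  `make_scenario1()`, `make_scenario2()`, `drive_eif_from_glm()` — an
  exponential integrate-and-fire network simulator with log-normal
  synaptic weights and the two benchmark scenarios (weak true coupling;
  no coupling but correlated per-trial input shifts).
* `lr_test_coupling()`, `single_neuron_glm_test()`, `fisher_combine()`,
  `rrr_test()`, `excursion_statistic()`, `excursion_permutation_test()`,
  `bonferroni_adjust()`, `power_curve()` — the inference and benchmarking
  suite.
* `read_spike_table()`, `pool_population()`, `make_dataset()`,
  `label_trials()`, `write_popglm_model()`, `run_manifest()`,
  `popglm_cli()` — IO, trial labelling (running if mean speed > 1 cm/s),
  model serialization and a command-line entry point
  (`inst/cli/popglm`).

## Worked example

Simulate a weakly coupled two-population EIF network, pool it, fit the
model and test the source-to-target coupling:

```r
library(popglm)
set.seed(1004)
sc <- make_scenario1(100)                       # 2 x 10 EIF neurons, 100 trials
ds <- make_dataset(sc$spikes, c("source", "target"))
ds$target
#> Pooled population spike train 'target': 100 trials x 500 bins (1 ms), 6970 spikes, 10 units pooled

res <- lr_test_coupling(ds, "target", "source", popglm_control(warp = FALSE))
res
#> pop-GLM likelihood-ratio test
#>   statistic = 21.2258, df = 8, p = 0.006571
```

The likelihood-ratio statistic compares the full model against a refit
with the source-to-target coupling filter forced to zero; here the weak
log-normal synapses (median unitary EPSP ~0.25 mV) are detected at
`p < 0.01` from 100 trials (across repeated simulations at this size the
test rejects in roughly half of runs, rising to ~0.9 by 200 trials).  The
fitted filter itself:

```r
fit <- fit_popglm(ds, "target", "source", popglm_control(warp = FALSE))
head(filter_curve(fit, "source", se = TRUE), 3)
#>   lag_ms      value         se
#> 1      1 0.02705571 0.02285480
#> 2      2 0.02864711 0.01673090
#> 3      3 0.02904575 0.01489085
```

a positive effect of a few percent on the target's log rate at short lags,
decaying within tens of milliseconds — the signature of weak excitatory
coupling.  On no-coupling data (`make_scenario1(100, coupled = FALSE)`)
the same test is calibrated (p-values roughly uniform).  The scenario-2
generator (`make_scenario2()`) produces correlated per-trial peak shifts
with no connectivity; fitting with `warp = TRUE` absorbs the shared
timing variability that otherwise produces spurious coupling.

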