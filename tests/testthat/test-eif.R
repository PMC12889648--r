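test_that("a quiet neuron at rest stays at the leak potential and never spikes", {
  sp <- simulate_eif_network(matrix(0, 1, 1), NULL, noise_sigma = 0,
                             duration_ms = 1000)
  expect_length(sp[[1]], 0)
})

test_that("the synaptic kernel is causal, non-negative and integrates to one", {
  syn <- synapse_params()
  t <- seq(0, 400, by = 0.01)
  expect_true(all(synaptic_kernel(-(1:10), syn) == 0))
  expect_true(all(synaptic_kernel(t, syn) >= 0))
  # analytic integral of (exp(-t/tau_d) - exp(-t/tau_r)) / (tau_d - tau_r)
  expect_equal((syn$tau_d_ms - syn$tau_r_ms) / (syn$tau_d_ms - syn$tau_r_ms), 1)
  expect_equal(sum(synaptic_kernel(t, syn)) * 0.01, 1, tolerance = 1e-4)
  expect_error(synapse_params(5, 5), "differ")
})

test_that("sampled synaptic weights follow the printed log-normal law", {
  set.seed(41)
  W <- sample_weights(300, 300)
  expect_true(all(W > 0))
  expect_equal(median(W), exp(-5.29), tolerance = 0.02)
  # analytic central-95% interval endpoints (printed as (0.0023, 0.0109))
  expect_equal(signif(qlnorm(0.025, -5.29, 0.4), 2), 0.0023)
  expect_equal(qlnorm(0.975, -5.29, 0.4), 0.0109, tolerance = 0.02)
})

test_that("refractoriness separates spikes by at least tau_ref", {
  set.seed(42)
  sp <- simulate_eif_network(matrix(0, 2, 2), NULL, noise_sigma = 8,
                             duration_ms = 5000)
  for (s in sp) {
    expect_gt(length(s), 10)
    expect_true(all(diff(s) >= 1 - 1e-9))
  }
})

test_that("halving the integration step changes the baseline rate by < 3%", {
  rate_at <- function(dt) {
    set.seed(43)
    sp <- simulate_eif_network(matrix(0, 1, 1), NULL, popglm:::EIF_NOISE_SIGMA,
                               duration_ms = 2e5, dt_ms = dt)
    length(sp[[1]]) / 200
  }
  r1 <- rate_at(0.05); r2 <- rate_at(0.025)
  expect_lt(abs(r2 - r1) / r1, 0.03)
  expect_error(simulate_eif_network(matrix(0, 1, 1), NULL, 1, 100, dt_ms = 0.2),
               "dt")
})

test_that("noise calibration hits the 10 Hz target and is monotone in sigma", {
  set.seed(44)
  sig <- calibrate_noise(duration_ms = 30000)
  set.seed(991)
  sp <- simulate_eif_network(matrix(0, 1, 1), NULL, as.numeric(sig),
                             duration_ms = 60000)
  expect_lt(abs(length(sp[[1]]) / 60 - 10) / 10, 0.1)
  rates <- vapply(c(2.5, 3.4, 4.5), function(s) {
    set.seed(45)
    length(simulate_eif_network(matrix(0, 1, 1), NULL, s, 30000)[[1]]) / 30
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_error(calibrate_noise(target_rate_hz = 0), "positive")
  expect_error(calibrate_noise(bracket = c(9, 10), duration_ms = 5000),
               "bracket")
})

test_that("scenario 1 produces the requested geometry and a dual-peaked PSTH", {
  set.seed(46)
  sc <- make_scenario1(20, n_per_pop = 10)
  expect_s3_class(sc, "scenario_data")
  expect_true(sc$coupled)
  expect_equal(length(unique(sc$spikes$trial_id)), 20)
  expect_equal(length(unique(sc$spikes$unit_id)), 20)
  for (p in c("source", "target")) {
    ps <- psth(sc$spikes, p, bin_ms = 10)
    expect_true(ps$time_ms[which.max(ps$rate_hz)] %in% seq(35, 95, by = 10))
    late <- ps[ps$time_ms > 150 & ps$time_ms < 350, ]
    expect_true(late$time_ms[which.max(late$rate_hz)] >= 200 &
                  late$time_ms[which.max(late$rate_hz)] <= 300)
  }
  # the no-coupling switch zeroes exactly the cross-population block
  set.seed(47)
  W1 <- popglm:::build_scenario_weights(10, coupled = TRUE)
  set.seed(47)
  W0 <- popglm:::build_scenario_weights(10, coupled = FALSE)
  expect_true(all(W0[11:20, 1:10] == 0))
  expect_true(all(W1[11:20, 1:10] > 0))
  expect_true(all(W0[1:10, 11:20] == 0))  # never target -> source
})

test_that("scenario 2 draws correlated peak times and supports zero correlation", {
  set.seed(48)
  sc <- make_scenario2(400, n_per_pop = 2)  # small populations: peak draws only need trials
  expect_false(sc$coupled)
  pk <- sc$peak_times
  expect_equal(cor(pk$source_peak1, pk$target_peak1), 0.5, tolerance = 0.3)
  expect_equal(cor(pk$source_peak2, pk$target_peak2), 0.9, tolerance = 0.1)
  expect_true(all(pk$source_peak1 > 0 & pk$source_peak1 < 150))
  expect_true(all(pk$source_peak2 > 150 & pk$source_peak2 < 350))
  set.seed(49)
  sc0 <- make_scenario2(400, n_per_pop = 2, peak_corr = c(0, 0))
  expect_lt(abs(cor(sc0$peak_times$source_peak1, sc0$peak_times$target_peak1)), 0.15)
  expect_error(make_scenario2(5, peak_corr = c(1.5, 0)), "correlations")
})

test_that("an EIF population driven by fitted GLM components shows the drive's two peaks", {
  set.seed(50)
  sc <- make_scenario1(30)
  ds <- make_dataset(sc$spikes, c("source", "target"))
  fit <- fit_popglm(ds, "target", "source", popglm_control(warp = FALSE))
  out <- drive_eif_from_glm(fit, ds, n_trials = 15, rescale = 0.2)
  ps <- out$psth
  early <- ps[ps$time_ms < 150, ]
  late <- ps[ps$time_ms > 150 & ps$time_ms < 350, ]
  base <- mean(ps$rate_hz[ps$time_ms > 400])
  expect_gt(max(early$rate_hz), 1.3 * base)
  expect_gt(max(late$rate_hz), 1.15 * base)
  out2 <- drive_eif_from_glm(fit, ds, n_trials = 15, rescale = 0.4)
  expect_gt(mean(out2$psth$rate_hz), mean(ps$rate_hz))
})
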