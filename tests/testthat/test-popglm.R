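test_that("with all filters and gains zero the log rate reduces to the baseline", {
  truth <- make_truth_popglm(self_amp = NULL)
  truth$couplings$source$coef[] <- 0
  cl <- list(target = rpois(500, 0.1), source = rpois(500, 0.1))
  lr <- popglm_log_rate(truth, cl)
  centers <- (1:500) - 0.5
  expect_equal(lr$log_rate, popglm:::eval_baseline(truth$baseline, centers),
               tolerance = 1e-12)
})

test_that("one source spike perturbs the log rate by exactly the coupling filter", {
  truth <- make_truth_popglm(self_amp = NULL)
  b <- 120
  src0 <- integer(500); src1 <- src0; src1[b] <- 1L
  tgt <- integer(500)
  lr0 <- popglm_log_rate(truth, list(target = tgt, source = src0))$log_rate
  lr1 <- popglm_log_rate(truth, list(target = tgt, source = src1))$log_rate
  fc <- filter_curve(truth, "source")
  delta <- lr1 - lr0
  expect_equal(delta[b + seq_len(100)], fc$value, tolerance = 1e-10)
  expect_true(all(delta[seq_len(b)] == 0))  # causal: no effect at or before the spike
})

test_that("the log rate equals the brute-force sum of its five terms", {
  set.seed(31)
  truth <- make_truth_popglm()
  truth$damp <- list(coef = rnorm(5, -0.5, 0.2), n = 5, lambda_max = 0.4,
                     tau_ms = 10)
  truth$gains <- c(-0.1, 0.25, -0.15)
  truth$warps <- list(identity_warp(500), build_warp(c(60, 250), c(70, 240)),
                      identity_warp(500))
  truth$trials <- 1:3
  centers <- (1:500) - 0.5
  for (m in 1:3) {
    y <- rpois(500, 0.15); s <- rpois(500, 0.12)
    lr <- popglm_log_rate(truth, list(target = y, source = s), trial = m)
    # independent per-term computation
    base <- popglm:::eval_baseline(truth$baseline,
                                   warp_inverse(truth$warps[[m]], centers))
    Bc <- raised_cosine_basis(8, 100, 10)
    conv <- function(x, vals) {
      out <- numeric(500)
      for (i in 1:500) {
        d <- seq_len(min(i - 1, 100))
        if (length(d)) out[i] <- sum(vals[d] * x[i - d])
      }
      out
    }
    selfterm <- conv(y, drop(Bc %*% truth$self$coef))
    cplterm <- conv(s, drop(Bc %*% truth$couplings$source$coef))
    lam <- compute_recent_activity(rep(which(y > 0) - 1, y[y > 0]), 10,
                                   (1:500) - 1)
    dampterm <- popglm:::eval_damp(truth$damp, lam)
    manual <- base + truth$gains[m] + selfterm + dampterm + cplterm
    expect_equal(lr$log_rate, manual, tolerance = 1e-8)
  }
})

test_that("with gains, warps and damping disabled the fit matches glm.fit on the same design", {
  set.seed(32)
  truth <- make_truth_popglm(cpl_amp = 0.6, self_amp = -0.3)
  src <- make_poisson_sources(40)
  sim <- simulate_popglm(truth, list(source = src), n_trials = 40)
  ds <- as_dataset(source = src, target = sim)
  ctl <- popglm_control(warp = FALSE, trial_gain = FALSE, damp_n = 0)
  fit <- fit_popglm(ds, "target", "source", ctl)
  des <- popglm:::build_popglm_design(ds, "target", "source", ctl,
                                      replicate(40, identity_warp(500),
                                                simplify = FALSE))
  ref <- suppressWarnings(
    glm.fit(des$X, des$y, family = poisson(),
            offset = rep(log(1), length(des$y))))
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$loglik,
               poisson_loglik(des$y, drop(des$X %*% coef(ref)), 1),
               tolerance = 1e-4)
})

test_that("refitting identical data gives bit-identical parameters", {
  set.seed(33)
  truth <- make_truth_popglm()
  src <- make_poisson_sources(15)
  sim <- simulate_popglm(truth, list(source = src), n_trials = 15)
  ds <- as_dataset(source = src, target = sim)
  ctl <- popglm_control(warp = FALSE)
  f1 <- fit_popglm(ds, "target", "source", ctl)
  f2 <- fit_popglm(ds, "target", "source", ctl)
  expect_identical(f1$coef, f2$coef)
  expect_identical(f1$gains, f2$gains)
})

test_that("the nested no-coupling fit never beats the full fit", {
  set.seed(34)
  truth <- make_truth_popglm()
  src <- make_poisson_sources(20)
  sim <- simulate_popglm(truth, list(source = src), n_trials = 20)
  ds <- as_dataset(source = src, target = sim)
  ctl <- popglm_control(warp = FALSE)
  full <- fit_popglm(ds, "target", "source", ctl)
  nested <- fit_popglm(ds, "target", character(0), ctl)
  expect_gte(full$loglik, nested$loglik - 1e-6 * abs(nested$loglik))
})

test_that("the alternating fit's log-likelihood trace is non-decreasing", {
  set.seed(35)
  nb <- 500; centers <- (1:nb) - 0.5
  base_lr <- log(0.15) + 1.2 * exp(-(centers - 60)^2 / 300) +
    exp(-(centers - 250)^2 / 900)
  M <- 25
  cnt <- matrix(0L, M, nb)
  for (m in 1:M) {
    w <- build_warp(c(60, 250), c(60 + rnorm(1, 0, 8),
                                  250 + rnorm(1, 0, 15)))
    lr <- approx(centers, base_lr, xout = warp_inverse(w, centers), rule = 2)$y
    cnt[m, ] <- rpois(nb, exp(lr))
  }
  ds <- as_dataset(target = as_pop_spikes(cnt, "target"))
  fit <- fit_popglm(ds, "target", character(0),
                    popglm_control(warp = TRUE, max_alternations = 8))
  expect_true(all(diff(fit$trace) >= -1e-6 * (abs(fit$loglik) + 1)))
  expect_gt(length(fit$trace), 1)
})

test_that("degenerate datasets are rejected with clear errors", {
  ds <- as_dataset(target = as_pop_spikes(matrix(0L, 4, 500), "target"))
  expect_error(fit_popglm(ds, "target", character(0),
                          popglm_control(warp = FALSE)), "no spikes")
  expect_error(fit_popglm(ds, "nope"), "not found")
  one <- as_dataset(target = as_pop_spikes(matrix(1L, 1, 500), "target"))
  expect_error(fit_popglm(one, "target", character(0)), "2 trials")
})

test_that("constant-rate simulation reproduces Poisson moments", {
  set.seed(36)
  truth <- make_truth_popglm(self_amp = NULL)
  truth$baseline$coef[] <- log(0.02)
  truth$baseline$mean_shift <- 0
  truth$couplings <- list()
  truth$sources <- character(0)
  sim <- simulate_popglm(truth, n_trials = 3000)
  totals <- rowSums(sim$counts)
  expect_equal(mean(totals), 10, tolerance = 0.06)
  expect_equal(var(totals), 10, tolerance = 0.12)
  expect_false(attr(sim, "unstable"))
})

test_that("a filter-free simulation converges to the inhomogeneous Poisson PSTH", {
  set.seed(37)
  truth <- make_truth_popglm(self_amp = NULL)
  truth$couplings <- list(); truth$sources <- character(0)
  n <- 6000
  sim <- simulate_popglm(truth, n_trials = n)
  centers <- (1:500) - 0.5
  mu <- exp(popglm:::eval_baseline(truth$baseline, centers))
  z <- (colMeans(sim$counts) - mu) / sqrt(mu / n)
  expect_lt(max(abs(z)), 5)  # ~Bonferroni bound over 500 bins
})

test_that("component contributions are additive and vanish for a zero model", {
  set.seed(38)
  truth <- make_truth_popglm()
  src <- make_poisson_sources(6)
  sim <- simulate_popglm(truth, list(source = src), n_trials = 6)
  ds <- as_dataset(source = src, target = sim)
  truth$trials <- 1:6
  truth$gains <- rep(0, 6)
  truth$warps <- replicate(6, identity_warp(500), simplify = FALSE)
  cc <- component_contributions(truth, ds)
  expect_equal(rowSums(cc), attr(cc, "log_rate"), tolerance = 1e-10)
  zero <- truth
  zero$baseline$coef[] <- 0
  zero$self$coef[] <- 0
  zero$couplings$source$coef[] <- 0
  cz <- component_contributions(zero, ds)
  expect_true(all(abs(cz) < 1e-12))
})

test_that("single-coupling contribution equals full log rate minus baseline", {
  truth <- make_truth_popglm(self_amp = NULL)
  s <- rpois(500, 0.2); y <- rpois(500, 0.1)
  lr <- popglm_log_rate(truth, list(target = y, source = s))
  expect_equal(lr$terms[, "coupling_source"],
               lr$log_rate - lr$terms[, "baseline"] - lr$terms[, "gain"],
               tolerance = 1e-10)
})
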