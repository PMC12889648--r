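test_that("Fisher's method matches its closed form and passes through single p-values", {
  f <- fisher_combine(c(0.5, 0.5))
  expect_equal(f$statistic, -4 * log(0.5), tolerance = 1e-10)  # 2.7726
  expect_equal(f$p_value, 0.5966, tolerance = 1e-3)
  expect_equal(f$df, 4)
  one <- fisher_combine(0.123)
  expect_equal(one$p_value, 0.123, tolerance = 1e-10)
  expect_error(fisher_combine(numeric(0)), "no p-values")
  expect_error(fisher_combine(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("Bonferroni adjustment multiplies, caps at one and validates m", {
  expect_equal(bonferroni_adjust(0.001, 30), 0.03)
  expect_equal(bonferroni_adjust(0.5, 30), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.7)), c(0.4, 1))
  expect_equal(bonferroni_adjust(0.04, 1), 0.04)
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "at least")
})

test_that("the excursion statistic handles identical curves and the triangle fixture", {
  g <- sin(seq(0, 3, length.out = 50))
  r0 <- excursion_statistic(g, g)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$delta_max, 0)
  # triangular bump of height 1 at t = 50 on [0, 100]
  t <- 0:100
  tri <- pmax(0, 1 - abs(t - 50) / 50)
  r <- excursion_statistic(numeric(101), tri, times = t)
  expect_equal(r$delta_max, 1)
  expect_equal(length(r$rois), 1)
  expect_equal(r$rois[[1]], c(25, 75))
  expect_equal(r$statistic, 37.5, tolerance = 1e-10)
})

test_that("disjoint bumps give multiple ROIs with the largest integral winning", {
  t <- 0:200
  g2 <- pmax(0, 1 - abs(t - 50) / 20) + 0.9 * pmax(0, 1 - abs(t - 150) / 20)
  r <- excursion_statistic(numeric(201), g2, times = t)
  expect_equal(length(r$rois), 2)
  expect_equal(r$statistic, max(r$roi_integrals))
  expect_gt(r$roi_integrals[1], r$roi_integrals[2])  # taller bump integrates more
})

test_that("the excursion statistic is symmetric, non-negative and scales linearly", {
  set.seed(51)
  t <- seq(0, 100, by = 1)
  g1 <- exp(-(t - 30)^2 / 100)
  g2 <- 0.4 * exp(-(t - 60)^2 / 200)
  a <- excursion_statistic(g1, g2, t)
  b <- excursion_statistic(g2, g1, t)
  expect_equal(a$statistic, b$statistic)
  expect_gt(a$statistic, 0)
  # scaling the difference by c >= 1 scales the statistic by c (single bump)
  base <- excursion_statistic(numeric(101), g1, t)$statistic
  for (c in c(1.5, 2, 3))
    expect_equal(excursion_statistic(numeric(101), c * g1, t)$statistic,
                 c * base, tolerance = 1e-10)
})

test_that("full-rank reduced-rank regression coincides with least squares", {
  set.seed(52)
  X <- scale(matrix(rnorm(200 * 6), 200, 6), scale = FALSE)
  Y <- scale(matrix(rnorm(200 * 4), 200, 4), scale = FALSE)
  B_full <- popglm:::rrr_coef(X, Y, rank = 4)
  B_ols <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(B_full, B_ols, tolerance = 1e-10)
  B_low <- popglm:::rrr_coef(X, Y, rank = 1)
  expect_equal(qr(B_low)$rank, 1)
})

test_that("the RRR permutation test is calibrated on independent populations", {
  set.seed(53)
  mk_noise_ds <- function() {
    as_dataset(source = as_pop_spikes(matrix(rpois(60 * 500, 0.12), 60, 500),
                                      "source"),
               target = as_pop_spikes(matrix(rpois(60 * 500, 0.12), 60, 500),
                                      "target"))
  }
  ps <- vapply(1:20, function(i) {
    rrr_test(mk_noise_ds(), "target", "source", n_perm = 60)$p_value
  }, numeric(1))
  expect_true(all(ps >= 1 / 61))            # add-one convention floor
  expect_gt(mean(ps), 0.25)                 # no systematic anti-conservatism
  expect_lt(mean(ps), 0.78)
  expect_error(rrr_test(mk_noise_ds(), "target", "source", rank = 50), "rank")
})

test_that("an empty coupling basis gives a null LR test by construction", {
  set.seed(54)
  ds <- as_dataset(source = as_pop_spikes(matrix(rpois(10 * 500, 0.1), 10, 500),
                                          "source"),
                   target = as_pop_spikes(matrix(rpois(10 * 500, 0.1), 10, 500),
                                          "target"))
  r <- lr_test_coupling(ds, "target", "source",
                        popglm_control(warp = FALSE, coupling_n = 0))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("the excursion permutation test validates inputs and respects the add-one floor", {
  set.seed(55)
  truth <- make_truth_popglm(cpl_amp = 0.5)
  src <- make_poisson_sources(40)
  sim <- simulate_popglm(truth, list(source = src), n_trials = 40)
  ds <- as_dataset(source = src, target = sim)
  labels <- rep(c("run", "stat"), each = 20)
  expect_error(excursion_permutation_test(ds, labels[1:10], "target", "source"),
               "one condition label per trial")
  expect_error(excursion_permutation_test(ds, rep("run", 40), "target", "source"),
               "two condition labels")
  expect_error(excursion_permutation_test(ds, labels, "target", "source",
                                          n_perm = 0), "n_perm")
  r <- excursion_permutation_test(ds, labels, "target", "source", n_perm = 19,
                                  control = popglm_control(warp = FALSE))
  expect_gte(r$p_value, 1 / 20)
  expect_lte(r$p_value, 1)
  expect_length(r$null_samples, 19)
})

test_that("a genuine condition difference in coupling is flagged by the excursion test", {
  set.seed(56)
  truth_lo <- make_truth_popglm(cpl_amp = 0.35)
  truth_hi <- make_truth_popglm(cpl_amp = 1.0)
  src <- make_poisson_sources(120)
  sim_lo <- simulate_popglm(truth_lo, list(source = src), n_trials = 60)
  src_hi <- src; src_hi$counts <- src$counts[61:120, ]; src_hi$trials <- 1:60
  sim_hi <- simulate_popglm(truth_hi, list(source = src_hi), n_trials = 60)
  ds <- as_dataset(
    source = as_pop_spikes(src$counts, "source"),
    target = as_pop_spikes(rbind(sim_lo$counts, sim_hi$counts), "target"))
  labels <- rep(c("lo", "hi"), each = 60)
  r <- excursion_permutation_test(ds, labels, "target", "source", n_perm = 39,
                                  control = popglm_control(warp = FALSE))
  expect_lt(r$p_value, 0.05)
  expect_gt(r$statistic, max(r$null_samples) * 0.99)
})

test_that("the power harness returns calibrated nulls and a power attribute", {
  res <- power_curve("rrr", trial_counts = 16, n_reps = 2, seed = 4,
                     rrr_n_perm = 40)
  expect_s3_class(res, "data.frame")
  expect_equal(nrow(res), 4)  # 2 reps x (coupled, null)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  pw <- attr(res, "power")
  expect_equal(nrow(pw), 2)
  res2 <- power_curve("rrr", trial_counts = 16, n_reps = 2, seed = 4,
                      rrr_n_perm = 40)
  expect_identical(res$p_value, res2$p_value)  # same seed, same outcome
})
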