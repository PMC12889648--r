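test_that("warps interpolate the six landmarks and keep the fixed anchors", {
  w <- build_warp(c(60, 250), c(80, 240))
  expect_equal(warp_evaluate(w, 30), 40)          # slope 80/60 on [0, 60]
  expect_equal(warp_inverse(w, 40), 30)
  expect_equal(warp_evaluate(w, c(0, 150, 350, 500)), c(0, 150, 350, 500))
  expect_equal(warp_evaluate(w, 60), 80)
})

test_that("identity warps and equal peak pairs act as the identity map", {
  expect_equal(warp_evaluate(identity_warp(), 123.4), 123.4)
  w <- build_warp(c(60, 250), c(60, 250))
  t <- seq(0, 500, by = 0.5)
  expect_equal(warp_evaluate(w, t), t, tolerance = 1e-12)
})

test_that("random legal warps are monotone bijections with exact round trips", {
  set.seed(5)
  grid <- seq(0, 500, by = 1)
  for (rep in 1:20) {
    tp <- c(runif(1, 5, 145), runif(1, 155, 345))
    rp <- c(runif(1, 5, 145), runif(1, 155, 345))
    w <- build_warp(tp, rp)
    fwd <- warp_evaluate(w, grid)
    expect_true(all(diff(fwd) > 0))
    expect_lt(max(abs(warp_inverse(w, fwd) - grid)), 1e-9)
  }
})

test_that("illegal peak positions are rejected", {
  expect_error(build_warp(c(60, 250), c(160, 250)), "peak1")
  expect_error(build_warp(c(60, 250), c(60, 360)), "peak1 < 150")
  expect_error(build_warp(c(0, 250), c(60, 250)), "template")
  expect_error(warp_evaluate(identity_warp(), 501), "outside")
})

test_that("template peaks are the windowed argmaxes with earliest-tie breaking", {
  f <- function(t) exp(-(t - 60)^2 / 200) + 0.8 * exp(-(t - 250)^2 / 800)
  expect_equal(detect_template_peaks(f), c(60, 250))
  # monotone decreasing: boundary argmaxes, clipped 1 ms inside the legal range
  expect_warning(p <- detect_template_peaks(function(t) -t), NA)
  expect_equal(p, c(1, 151))
  # symmetric double maximum on [0,150]: earliest wins
  g <- function(t) ifelse(t <= 150, exp(-(t - 50)^2 / 50) + exp(-(t - 100)^2 / 50),
                          exp(-(t - 250)^2 / 800))
  expect_equal(detect_template_peaks(g)[1], 50)
})

test_that("trial peaks are recovered from high-rate data with a known shift", {
  set.seed(21)
  nb <- 500; centers <- (1:nb) - 0.5
  base_lr <- log(1.0) + 1.6 * exp(-(centers - 60)^2 / 300) +
    1.4 * exp(-(centers - 250)^2 / 900)
  baseline <- list(coef = popglm:::project_onto_basis(
    base_lr, popglm:::bspline_basis(centers, 25, c(0, 500)))$coef,
    df = 25, range = c(0, 500), drop_first = FALSE, mean_shift = 0)
  M <- 30
  cnt <- matrix(0L, M, nb)
  for (m in 1:M) {
    w <- build_warp(c(60, 250), c(60, 270))  # +20 ms shift on peak 2
    lr <- approx(centers, base_lr, xout = warp_inverse(w, centers), rule = 2)$y
    cnt[m, ] <- rpois(nb, exp(lr))
  }
  inc <- replicate(M, identity_warp(500), simplify = FALSE)
  up <- estimate_trial_peaks(cnt, matrix(0, M, nb), baseline, inc)
  hit <- mean(abs(up$peaks[, 2] - 270) <= 4)  # within 2x the 2-ms grid step
  expect_gte(hit, 0.9)
})

test_that("peak search keeps the incumbent for silent trials and never lowers the likelihood", {
  set.seed(22)
  nb <- 500; centers <- (1:nb) - 0.5
  base_lr <- log(0.2) + exp(-(centers - 60)^2 / 300) + exp(-(centers - 250)^2 / 900)
  baseline <- list(coef = popglm:::project_onto_basis(
    base_lr, popglm:::bspline_basis(centers, 25, c(0, 500)))$coef,
    df = 25, range = c(0, 500), drop_first = FALSE, mean_shift = 0)
  cnt <- rbind(rpois(nb, exp(base_lr)), 0L)  # second trial silent
  # anchor the incumbents at the template peaks the search itself will use
  tp <- detect_template_peaks(function(t) popglm:::eval_baseline(baseline, t))
  inc <- list(build_warp(tp, c(70, 260)), build_warp(tp, c(70, 260)))
  ll_before <- vapply(1:2, function(m) {
    w <- inc[[m]]
    lr <- popglm:::eval_baseline(baseline, warp_inverse(w, centers))
    poisson_loglik(cnt[m, ], lr, 1)
  }, numeric(1))
  up <- estimate_trial_peaks(cnt, matrix(0, 2, nb), baseline, inc)
  expect_equal(up$peaks[2, ], c(70, 260))  # incumbent retained, no evidence
  ll_after <- vapply(1:2, function(m) {
    lr <- popglm:::eval_baseline(baseline, warp_inverse(up$warps[[m]], centers))
    poisson_loglik(cnt[m, ], lr, 1)
  }, numeric(1))
  expect_true(all(ll_after >= ll_before - 1e-8))
})
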