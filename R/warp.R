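#' Construct a piecewise-linear trial time warp
#'
#' A warp maps template time to trial time through six landmark pairs:
#' `(0,0)`, `(p1_template, p1_trial)`, `(150,150)`, `(p2_template,
#' p2_trial)`, `(350,350)`, `(T,T)`.  The first response peak must lie in
#' `(0,150)` and the second in `(150,350)`, which guarantees a strictly
#' monotone bijection of `[0,T]`.
#'
#' @param template_peaks numeric length-2: template peak times (ms).
#' @param trial_peaks numeric length-2: trial-specific peak times (ms).
#' @param T trial duration in ms (default 500).
#' @return object of class `warp_fn` with fields `template_times`,
#'   `trial_times`.
#' @export
#' @examples
#' w <- build_warp(c(60, 250), c(80, 240))
#' warp_evaluate(w, 30)     # 40: slope 80/60 on the first segment
#' warp_inverse(w, 40)      # 30
build_warp <- function(template_peaks, trial_peaks, T = 500) {
  check_peaks <- function(p, what) {
    if (length(p) != 2 || any(!is.finite(p)))
      stop(what, " must be two finite peak times")
    if (!(p[1] > 0 && p[1] < 150 && p[2] > 150 && p[2] < 350))
      stop(what, " must satisfy 0 < peak1 < 150 < peak2 < 350 (got ",
           paste(signif(p, 6), collapse = ", "), ")")
  }
  check_peaks(template_peaks, "`template_peaks`")
  check_peaks(trial_peaks, "`trial_peaks`")
  structure(list(
    template_times = c(0, template_peaks[1], 150, template_peaks[2], 350, T),
    trial_times    = c(0, trial_peaks[1],    150, trial_peaks[2],    350, T),
    T = T), class = "warp_fn")
}

#' Identity warp on `[0, T]`
#' @param T trial duration (ms).
#' @return a `warp_fn` that maps every time to itself.
#' @export
identity_warp <- function(T = 500) {
  structure(list(template_times = c(0, 75, 150, 250, 350, T),
                 trial_times    = c(0, 75, 150, 250, 350, T),
                 T = T), class = "warp_fn")
}

#' Evaluate a warp (template time -> trial time)
#' @param warp a `warp_fn`.
#' @param t times in `[0, T]`.
#' @export
warp_evaluate <- function(warp, t) {
  if (any(t < 0 | t > warp$T)) stop("warp evaluated outside [0, T]")
  stats::approx(warp$template_times, warp$trial_times, xout = t,
                method = "linear", ties = "ordered")$y
}

#' Invert a warp (trial time -> template time)
#' @inheritParams warp_evaluate
#' @export
warp_inverse <- function(warp, t) {
  if (any(t < 0 | t > warp$T)) stop("warp inverted outside [0, T]")
  stats::approx(warp$trial_times, warp$template_times, xout = t,
                method = "linear", ties = "ordered")$y
}

#' @export
print.warp_fn <- function(x, ...) {
  cat("Piecewise-linear time warp on [0, ", x$T, "] ms\n", sep = "")
  cat("  template peaks: ", x$template_times[2], ", ", x$template_times[4],
      " -> trial peaks: ", signif(x$trial_times[2], 5), ", ",
      signif(x$trial_times[4], 5), "\n", sep = "")
  invisible(x)
}

is_identity_warp <- function(warp) {
  all(warp$template_times == warp$trial_times)
}

#' Locate the two response peaks of a baseline template
#'
#' The first peak is the argmax of the template on `[0, 150]` ms, the second
#' the argmax on `[150, 350]` ms, both evaluated on a 1-ms grid with ties
#' broken to the earliest time.  Peaks are clipped 1 ms inside the open
#' intervals required by [build_warp()].
#'
#' @param template_fun function of time returning template values, or a
#'   `popglm_fit` (whose baseline template is used).
#' @param T trial duration (ms).
#' @return numeric length-2 vector `(peak1_ms, peak2_ms)`.
#' @export
detect_template_peaks <- function(template_fun, T = 500) {
  if (inherits(template_fun, "popglm_fit")) {
    fit <- template_fun
    template_fun <- function(t) eval_baseline(fit$baseline, t)
  }
  g1 <- seq(0, 150, by = 1)
  g2 <- seq(150, min(350, T), by = 1)
  v1 <- template_fun(g1)
  v2 <- template_fun(g2)
  if (max(v1) - min(v1) < sqrt(.Machine$double.eps) ||
      max(v2) - min(v2) < sqrt(.Machine$double.eps))
    warning("flat template segment; using earliest argmax")
  p1 <- g1[which.max(v1)]
  p2 <- g2[which.max(v2)]
  c(min(max(p1, 1), 149), min(max(p2, 151), 349))
}

#' Estimate trial-specific peak times by likelihood grid search
#'
#' For each trial, candidate peak positions around the template peaks are
#' scored by the trial's Poisson log-likelihood with all non-baseline model
#' terms held fixed; the best pair is kept.  The two peaks are searched
#' coordinate-wise (peak 1 with peak 2 fixed, then peak 2), and a candidate
#' replaces the incumbent only if its exactly evaluated likelihood is at
#' least as high, so the per-trial likelihood never decreases relative to
#' the incumbent trial peaks re-anchored at the current template peaks
#' (the template, and hence its detected peaks, can move between
#' alternations).  Trials with no spikes retain the incumbent peaks.
#'
#' @param counts trials x bins matrix of target population counts.
#' @param rest_eta matrix like `counts` holding the fixed part of the log
#'   rate (gain + self-history + damping + coupling), excluding the baseline.
#' @param baseline baseline template (list with `coef`, `df`, `range`, ...)
#'   as stored in a `popglm_fit`.
#' @param incumbent list of `warp_fn`, one per trial.
#' @param bin_ms,duration_ms bin geometry.
#' @param halfwidth_ms,step_ms search grid extent and step around the
#'   template peaks (defaults 40 and 2 ms).
#' @return list with `warps` (per-trial `warp_fn`), `peaks` (trials x 2),
#'   `loglik` (total, Poisson, all bins).
#' @export
estimate_trial_peaks <- function(counts, rest_eta, baseline, incumbent,
                                 bin_ms = 1, duration_ms = 500,
                                 halfwidth_ms = 40, step_ms = 2) {
  T <- duration_ms
  centers <- (seq_len(ncol(counts)) - 0.5) * bin_ms
  tpl_peaks <- detect_template_peaks(function(t) eval_baseline(baseline, t), T)
  # dense template for fast candidate sweeps; exact spline eval for acceptance
  tgrid <- seq(0, T, by = 0.25)
  tvals <- eval_baseline(baseline, tgrid)
  cand_grid <- function(center, lo, hi) {
    g <- seq(center - halfwidth_ms, center + halfwidth_ms, by = step_ms)
    g[g > lo & g < hi]
  }
  cand1 <- cand_grid(tpl_peaks[1], 1, 149)
  cand2 <- cand_grid(tpl_peaks[2], 151, 349)
  eta_base_interp <- function(p1, p2) {
    tt <- stats::approx(c(0, p1, 150, p2, 350, T),
                        c(0, tpl_peaks[1], 150, tpl_peaks[2], 350, T),
                        xout = centers, ties = "ordered")$y
    stats::approx(tgrid, tvals, xout = tt, ties = "ordered")$y
  }
  eta_base_exact <- function(p1, p2) {
    tt <- stats::approx(c(0, p1, 150, p2, 350, T),
                        c(0, tpl_peaks[1], 150, tpl_peaks[2], 350, T),
                        xout = centers, ties = "ordered")$y
    eval_baseline(baseline, tt)
  }
  part_ll <- function(y, eta) sum(y * eta) - bin_ms * sum(exp(eta))
  n_trials <- nrow(counts)
  peaks <- matrix(NA_real_, n_trials, 2)
  warps <- vector("list", n_trials)
  for (m in seq_len(n_trials)) {
    y <- counts[m, ]
    rest <- rest_eta[m, ]
    inc <- incumbent[[m]]
    p1 <- inc$trial_times[2]; p2 <- inc$trial_times[4]
    # map incumbent onto template-peak parameterisation when templates moved
    if (sum(y) > 0 && length(cand1) && length(cand2)) {
      best <- c(p1, p2)
      for (dim in 1:2) {
        cc <- if (dim == 1) cand1 else cand2
        lls <- vapply(cc, function(p) {
          pp <- best; pp[dim] <- p
          part_ll(y, eta_base_interp(pp[1], pp[2]) + rest)
        }, numeric(1))
        best[dim] <- cc[which.max(lls)]
      }
      # exact accept test against incumbent
      ll_new <- part_ll(y, eta_base_exact(best[1], best[2]) + rest)
      ll_inc <- part_ll(y, eta_base_exact(p1, p2) + rest)
      if (ll_new >= ll_inc) { p1 <- best[1]; p2 <- best[2] }
    } else if (!length(cand1) || !length(cand2)) {
      warning("empty peak search grid after clipping; keeping incumbent")
    }
    peaks[m, ] <- c(p1, p2)
    warps[[m]] <- build_warp(tpl_peaks, c(p1, p2), T = T)
  }
  eta <- rest_eta
  for (m in seq_len(n_trials))
    eta[m, ] <- eta_base_exact(peaks[m, 1], peaks[m, 2]) + rest_eta[m, ]
  ll <- sum(stats::dpois(as.vector(counts), exp(as.vector(eta)) * bin_ms, log = TRUE))
  list(warps = warps, peaks = peaks, loglik = ll, template_peaks = tpl_peaks)
}
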