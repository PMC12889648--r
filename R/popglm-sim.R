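#' Forward-simulate a fitted pop-GLM
#'
#' Generates target-population spike counts bin by bin: each bin's count is
#' drawn `Poisson(exp(log_rate) * bin_ms)`, where the log rate is conditioned
#' on the spikes simulated so far (self-history convolution and damping term
#' updated online) plus the fixed baseline/gain/coupling contributions.  The
#' rate is clipped at `fit$control$rate_ceiling_hz`; any clipped bin raises
#' the per-trial instability flag.
#'
#' @param fit a `popglm_fit` (or a parameter list of the same shape).
#' @param source_data named list of `pop_spikes` for the source populations
#'   (required if the model has coupling filters); trial `m` of the sources
#'   drives simulated trial `m`.
#' @param n_trials number of trials to simulate.  Defaults to the number of
#'   source trials (or of fitted trials for a source-free model).  When it
#'   exceeds the number of source trials, source trials are recycled.
#' @param use_warps apply the fitted per-trial warps/gains (recycled), or
#'   the identity warp and zero gain (`FALSE`, default for new data)?
#' @return object of class `pop_spikes` for the simulated target, with
#'   attributes `instability` (logical per trial) and `unstable` (any trial
#'   clipped).
#' @export
simulate_popglm <- function(fit, source_data = NULL, n_trials = NULL,
                            use_warps = FALSE) {
  n_bins <- fit$n_bins; bin_ms <- fit$bin_ms
  centers <- (seq_len(n_bins) - 0.5) * bin_ms
  if (length(fit$sources)) {
    missing_src <- setdiff(fit$sources, names(source_data))
    if (length(missing_src))
      stop("missing source trains for: ", paste(missing_src, collapse = ", "))
    n_src_trials <- nrow(source_data[[fit$sources[1]]]$counts)
  } else n_src_trials <- length(fit$trials)
  if (is.null(n_trials)) n_trials <- n_src_trials

  self_vals <- if (!is.null(fit$self))
    drop(raised_cosine_basis(fit$self$n, fit$self$support_ms,
                             fit$self$log_stretch, bin_ms) %*% fit$self$coef)
  else numeric(0)
  if (!is.null(fit$damp)) {
    lam_grid <- seq(0, fit$damp$lambda_max, length.out = 256)
    damp_grid <- eval_damp(fit$damp, lam_grid)
    damp_max <- fit$damp$lambda_max
    tau <- fit$damp$tau_ms
  } else {
    damp_grid <- numeric(0); damp_max <- 0
    tau <- fit$control$tau_ms
  }
  ceiling_per_ms <- fit$control$rate_ceiling_hz / 1000

  counts <- matrix(0L, n_trials, n_bins)
  instab <- logical(n_trials)
  cpl_bases <- lapply(fit$couplings, function(f)
    raised_cosine_basis(f$n, f$support_ms, f$log_stretch, bin_ms))
  for (m in seq_len(n_trials)) {
    src_m <- ((m - 1) %% n_src_trials) + 1
    if (use_warps) {
      fm <- ((m - 1) %% length(fit$trials)) + 1
      warp <- fit$warps[[fm]]; gain <- fit$gains[fm]
    } else {
      warp <- identity_warp(fit$duration_ms); gain <- 0
    }
    tt <- if (is_identity_warp(warp)) centers else warp_inverse(warp, centers)
    offset <- eval_baseline(fit$baseline, tt) + gain
    for (s in fit$sources) {
      y_s <- source_data[[s]]$counts[src_m, ]
      offset <- offset + drop(convolve_counts(matrix(y_s, 1), cpl_bases[[s]]) %*%
                                fit$couplings[[s]]$coef)
    }
    sim <- popglm_simulate_cpp(offset, self_vals, damp_grid, damp_max,
                               tau, bin_ms, ceiling_per_ms)
    counts[m, ] <- sim$counts
    instab[m] <- sim$clipped
  }
  out <- structure(list(population_id = fit$target, counts = counts,
                        trials = seq_len(n_trials), bin_ms = bin_ms,
                        duration_ms = fit$duration_ms, n_units = NA_integer_),
                   class = "pop_spikes")
  attr(out, "instability") <- instab
  attr(out, "unstable") <- any(instab)
  out
}
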