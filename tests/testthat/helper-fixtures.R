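# Shared fixtures: hand-built pop-GLM truths and small pooled datasets,
# generated in code at test time.

# A pop_spikes object from a counts matrix.
as_pop_spikes <- function(counts, id = "pop", bin_ms = 1, duration_ms = ncol(counts) * bin_ms) {
  structure(list(population_id = id, counts = counts,
                 trials = seq_len(nrow(counts)), bin_ms = bin_ms,
                 duration_ms = duration_ms, n_units = 10L),
            class = "pop_spikes")
}

as_dataset <- function(...) {
  out <- list(...)
  class(out) <- "pop_dataset"
  out
}

# Ground-truth pop-GLM parameters with a dual-bump baseline, an
# exponential-decay coupling filter and (optionally) a mild negative
# self-history filter.  No gains, identity warps, no damping term.
make_truth_popglm <- function(baseline_df = 25, cpl_amp = 0.9, self_amp = -0.4,
                              base_rate = 0.08, n_bins = 500,
                              rate_ceiling_hz = 1e6) {
  centers <- seq_len(n_bins) - 0.5
  Bc <- raised_cosine_basis(8, 100, 10)
  lag <- attr(Bc, "lag_ms")
  cpl_coef <- popglm:::project_onto_basis(cpl_amp * exp(-lag / 12), Bc)$coef
  base_lr <- log(base_rate) + 0.9 * exp(-(centers - 60)^2 / 450) +
    0.7 * exp(-(centers - 250)^2 / 1800)
  Bb <- popglm:::bspline_basis(centers, baseline_df, c(0, n_bins))
  bcoef <- popglm:::project_onto_basis(base_lr, Bb)$coef
  self <- if (!is.null(self_amp))
    list(coef = popglm:::project_onto_basis(self_amp * exp(-lag / 8), Bc)$coef,
         n = 8, support_ms = 100, log_stretch = 10)
  structure(list(
    target = "target", sources = "source",
    baseline = list(coef = bcoef, df = baseline_df, range = c(0, n_bins),
                    drop_first = FALSE, mean_shift = 0),
    gains = 0, warps = list(identity_warp(n_bins)),
    self = self, damp = NULL,
    couplings = list(source = list(coef = cpl_coef, n = 8, support_ms = 100,
                                   log_stretch = 10)),
    control = popglm_control(warp = FALSE, rate_ceiling_hz = rate_ceiling_hz),
    trials = 1, bin_ms = 1, duration_ms = n_bins, n_bins = n_bins),
    class = "popglm_fit")
}

# Inhomogeneous-Poisson source trains with the fixture's dual-bump profile.
make_poisson_sources <- function(n_trials, n_bins = 500, base_rate = 0.1) {
  centers <- seq_len(n_bins) - 0.5
  lam <- base_rate * (1 + 2 * exp(-(centers - 60)^2 / 450) +
                        1.2 * exp(-(centers - 250)^2 / 1800))
  as_pop_spikes(matrix(stats::rpois(n_trials * n_bins, rep(lam, each = n_trials)),
                       n_trials, n_bins), id = "source")
}

# Tiny spike table with exact spike times (two populations, two units each).
tiny_spike_table <- function() {
  data.frame(
    population_id = c("a", "a", "a", "b", "b"),
    trial_id = c(1, 1, 2, 1, 2),
    unit_id = c("a1", "a2", "a1", "b1", "b1"),
    spike_time_ms = c(10.5, 10.7, 250.123456, 5.25, 499.9),
    stringsAsFactors = FALSE)
}
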