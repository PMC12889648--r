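#' Label trials as running or stationary from speed traces
#'
#' A trial is labelled `"running"` when its average speed strictly exceeds
#' the threshold (default 1 cm/s), otherwise `"stationary"`.
#'
#' @param speed_traces list of per-trial speed traces (cm/s), or a matrix
#'   with one row per trial.
#' @param threshold_cm_s running threshold (default 1).
#' @param trial_ids optional trial identifiers.
#' @return data.frame with `trial_id`, `mean_speed_cm_s`, `condition`.
#' @export
label_trials <- function(speed_traces, threshold_cm_s = 1.0,
                         trial_ids = NULL) {
  if (is.matrix(speed_traces))
    speed_traces <- split(speed_traces, row(speed_traces))
  if (any(!vapply(speed_traces, length, 1L)))
    stop("empty speed trace(s): ",
         paste(which(!vapply(speed_traces, length, 1L)), collapse = ", "))
  ms <- vapply(speed_traces, mean, numeric(1))
  if (any(ms < 0)) stop("negative mean speed")
  if (is.null(trial_ids)) trial_ids <- seq_along(speed_traces)
  data.frame(trial_id = trial_ids, mean_speed_cm_s = ms,
             condition = ifelse(ms > threshold_cm_s, "running", "stationary"),
             stringsAsFactors = FALSE)
}

#' Serialize a fitted pop-GLM to structured text (JSON)
#'
#' All coefficient vectors, spline geometry, warp landmark pairs, tau, and
#' the control list are written with full floating-point precision, so the
#' model round-trips through [read_popglm_model()] exactly.
#'
#' @param fit a `popglm_fit`.
#' @param path output path.
#' @export
write_popglm_model <- function(fit, path) {
  ser <- list(
    format = "popglm-model", version = 1,
    target = fit$target, sources = fit$sources,
    baseline = fit$baseline, gains = fit$gains,
    warps = lapply(fit$warps, function(w)
      list(template_times = w$template_times, trial_times = w$trial_times,
           T = w$T)),
    self = fit$self, damp = fit$damp, couplings = fit$couplings,
    loglik = fit$loglik, trace = fit$trace, converged = fit$converged,
    trials = fit$trials, bin_ms = fit$bin_ms, duration_ms = fit$duration_ms,
    n_bins = fit$n_bins, train_mean_rate_hz = fit$train_mean_rate_hz,
    control = unclass(fit$control))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a serialized pop-GLM model
#' @param path path written by [write_popglm_model()].
#' @return a `popglm_fit` (without the design-dependent Fisher information).
#' @export
read_popglm_model <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(s$format, "popglm-model"))
    stop("not a popglm model file: ", path)
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  warps <- lapply(s$warps, function(w)
    structure(list(template_times = num(w$template_times),
                   trial_times = num(w$trial_times), T = w$T),
              class = "warp_fn"))
  filt <- function(f) if (is.null(f)) NULL else
    list(coef = num(f$coef), n = f$n, support_ms = f$support_ms,
         log_stretch = f$log_stretch)
  baseline <- s$baseline
  baseline$coef <- num(baseline$coef)
  baseline$range <- num(baseline$range)
  damp <- if (is.null(s$damp)) NULL else
    list(coef = num(s$damp$coef), n = s$damp$n,
         lambda_max = s$damp$lambda_max, tau_ms = s$damp$tau_ms)
  ctl <- lapply(s$control, function(v) if (is.list(v)) unlist(v) else v)
  class(ctl) <- "popglm_control"
  structure(list(target = s$target, sources = as.character(unlist(s$sources)),
                 baseline = baseline, gains = num(s$gains), warps = warps,
                 self = filt(s$self), damp = damp,
                 couplings = lapply(s$couplings, filt),
                 loglik = s$loglik, trace = num(s$trace),
                 converged = s$converged,
                 coef = NULL, cols = NULL, fisher = NULL, control = ctl,
                 trials = unlist(s$trials), bin_ms = s$bin_ms,
                 duration_ms = s$duration_ms, n_bins = s$n_bins,
                 train_mean_rate_hz = s$train_mean_rate_hz),
            class = "popglm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adler-32 digest (hex string) of a character/raw payload; vectorised, used
# for config hashes and input-file digests in run manifests.
fnv1a_hex <- function(x) {
  if (is.character(x)) x <- charToRaw(paste(x, collapse = "\n"))
  b <- as.numeric(x)
  n <- length(b)
  if (n == 0) return("00000001")
  A <- 1; B <- 0
  for (start in seq(1, n, by = 500000L)) {  # chunked to stay in exact-double range
    chunk <- b[start:min(start + 499999L, n)]
    k <- length(chunk)
    B <- (B + k * A + sum(chunk * (k - seq_len(k) + 1))) %% 65521
    A <- (A + sum(chunk)) %% 65521
  }
  sprintf("%04x%04x", as.integer(B), as.integer(A))
}

#' Build (and optionally write) a run manifest
#'
#' Records the seed, package version, configuration snapshot (with a stable
#' hash), and digests of input files, so that deterministic stages can be
#' reproduced bit for bit.
#'
#' @param config list of configuration values.
#' @param seed integer seed used for the run.
#' @param input_files character vector of input paths to digest.
#' @param path optional output path (JSON).
#' @return the manifest list, invisibly if written.
#' @export
run_manifest <- function(config = list(), seed = NA_integer_,
                         input_files = character(0), path = NULL) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  digests <- lapply(input_files, function(f) {
    if (!file.exists(f)) stop("input file not found: ", f)
    fnv1a_hex(readBin(f, "raw", file.info(f)$size))
  })
  names(digests) <- input_files
  man <- list(package = "popglm",
              version = as.character(utils::packageVersion("popglm")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, config = config,
              config_hash = fnv1a_hex(as.character(cfg_json)),
              input_digests = digests)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(man))
  }
  man
}
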