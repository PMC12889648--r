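#' Read a spike table from delimited text
#'
#' The on-disk format is comma-separated text with header columns
#' `population_id`, `trial_id`, `unit_id`, `spike_time_ms` (one row per
#' spike).  Spike times are in milliseconds from trial onset.
#'
#' @param path file path.
#' @param duration_ms optional trial duration; rows with times beyond it are
#'   rejected.
#' @return data.frame with the four columns above.
#' @export
read_spike_table <- function(path, duration_ms = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("population_id", "trial_id", "unit_id", "spike_time_ms")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("spike table is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[required]
  bad <- which(!is.finite(df$spike_time_ms) | df$spike_time_ms < 0)
  if (!is.null(duration_ms))
    bad <- union(bad, which(df$spike_time_ms > duration_ms))
  if (length(bad))
    stop("invalid spike times at rows: ", paste(utils::head(sort(bad), 20L), collapse = ", "))
  df
}

#' Write a spike table to delimited text
#'
#' @param spikes data.frame with columns `population_id`, `trial_id`,
#'   `unit_id`, `spike_time_ms`.
#' @param path file path.
#' @export
write_spike_table <- function(spikes, path) {
  required <- c("population_id", "trial_id", "unit_id", "spike_time_ms")
  if (!all(required %in% names(spikes)))
    stop("spike table is missing columns: ",
         paste(setdiff(required, names(spikes)), collapse = ", "))
  utils::write.csv(spikes[required], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pool a population spike train from single-unit spikes
#'
#' Sums per-bin spike counts over the units of one population, yielding the
#' pooled population spike train the model works on.  Counts above 1 per bin
#' are expected for pooled trains.
#'
#' @param spikes spike table (see [read_spike_table()]).
#' @param population_id which population to pool.
#' @param neuron_subset unit ids to include; default all units observed for
#'   this population.  Unknown ids are an error.
#' @param bin_ms bin width in ms (default 1).
#' @param duration_ms trial duration T in ms (default 500).
#' @param trials trial ids defining rows of the count matrix; defaults to all
#'   trial ids present anywhere in `spikes` (so silent trials keep a row).
#' @return object of class `pop_spikes`: list with `population_id`, `counts`
#'   (trials x bins integer matrix), `trials`, `bin_ms`, `duration_ms`.
#' @export
pool_population <- function(spikes, population_id, neuron_subset = NULL,
                            bin_ms = 1, duration_ms = 500, trials = NULL) {
  sub <- spikes[spikes$population_id == population_id, , drop = FALSE]
  units_here <- unique(sub$unit_id)
  if (is.null(neuron_subset)) {
    neuron_subset <- units_here
  } else {
    unknown <- setdiff(neuron_subset, units_here)
    if (length(unknown))
      stop("unknown unit ids for population ", population_id, ": ",
           paste(unknown, collapse = ", "))
    sub <- sub[sub$unit_id %in% neuron_subset, , drop = FALSE]
  }
  if (is.null(trials)) trials <- sort(unique(spikes$trial_id))
  n_bins <- round(duration_ms / bin_ms)
  counts <- matrix(0L, nrow = length(trials), ncol = n_bins)
  rownames(counts) <- as.character(trials)
  if (nrow(sub)) {
    bin <- pmin(floor(sub$spike_time_ms / bin_ms) + 1L, n_bins)
    tr <- match(sub$trial_id, trials)
    if (anyNA(tr)) stop("spike rows reference trials not in `trials`")
    tab <- table(factor(tr, levels = seq_along(trials)),
                 factor(bin, levels = seq_len(n_bins)))
    counts <- matrix(as.integer(tab), nrow = length(trials))
    rownames(counts) <- as.character(trials)
  }
  structure(list(population_id = population_id, counts = counts,
                 trials = trials, bin_ms = bin_ms, duration_ms = duration_ms,
                 n_units = length(neuron_subset)),
            class = "pop_spikes")
}

#' @export
print.pop_spikes <- function(x, ...) {
  cat("Pooled population spike train '", x$population_id, "': ",
      nrow(x$counts), " trials x ", ncol(x$counts), " bins (",
      x$bin_ms, " ms), ", sum(x$counts), " spikes, ",
      x$n_units, " units pooled\n", sep = "")
  invisible(x)
}

#' Assemble a multi-population dataset of pooled spike trains
#'
#' @param spikes spike table.
#' @param populations population ids to pool (default all present).
#' @param neuron_subsets optional named list of unit subsets per population.
#' @inheritParams pool_population
#' @return named list of [pool_population()] results, class `pop_dataset`.
#' @export
make_dataset <- function(spikes, populations = NULL, neuron_subsets = NULL,
                         bin_ms = 1, duration_ms = 500) {
  if (is.null(populations)) populations <- unique(spikes$population_id)
  trials <- sort(unique(spikes$trial_id))
  out <- lapply(populations, function(p)
    pool_population(spikes, p, neuron_subset = neuron_subsets[[p]],
                    bin_ms = bin_ms, duration_ms = duration_ms,
                    trials = trials))
  names(out) <- populations
  structure(out, class = "pop_dataset")
}

# Validate that all populations of a dataset share the trial set and bin grid;
# returns the common geometry.
dataset_geometry <- function(dataset) {
  stopifnot(length(dataset) >= 1)
  ref <- dataset[[1]]
  for (p in dataset) {
    if (!identical(p$trials, ref$trials) ||
        p$bin_ms != ref$bin_ms || p$duration_ms != ref$duration_ms)
      stop("populations do not share the same trials / bin grid")
  }
  list(trials = ref$trials, n_trials = length(ref$trials),
       bin_ms = ref$bin_ms, duration_ms = ref$duration_ms,
       n_bins = ncol(ref$counts))
}

# Per-unit binned counts for one population: list(unit -> trials x bins matrix).
bin_units <- function(spikes, population_id, bin_ms = 1, duration_ms = 500,
                      trials = NULL) {
  sub <- spikes[spikes$population_id == population_id, , drop = FALSE]
  units <- sort(unique(sub$unit_id))
  if (is.null(trials)) trials <- sort(unique(spikes$trial_id))
  out <- lapply(units, function(u)
    pool_population(spikes, population_id, neuron_subset = u,
                    bin_ms = bin_ms, duration_ms = duration_ms,
                    trials = trials)$counts)
  names(out) <- as.character(units)
  out
}
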