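#' Binned neural population dataset
#'
#' The universal input record of the package: a time-by-neuron matrix of
#' binned spike counts, time-aligned 2-D velocity kinematics, the bin width in
#' seconds, and optional trial structure. Counts are stored as doubles because
#' smoothing produces fractional values; integer counts are promoted.
#'
#' @param counts Numeric matrix, `T` time bins by `N` neurons, non-negative.
#' @param kinematics Numeric matrix, `T` by 2, velocity components
#'   (`vx`, `vy`) in arbitrary but consistent units.
#' @param bin_width Bin width in seconds (default 0.1, i.e. 100 ms bins).
#' @param trial_id Integer vector of length `T` assigning each bin to a trial;
#'   `-1` marks untrialed bins. Bins belonging to one trial must be contiguous.
#'   Default: a single trial spanning the whole recording.
#' @param condition_id Optional integer vector, one entry per *trial* (in the
#'   order trials first appear), giving a task condition label (e.g. reach
#'   direction).
#' @param allow_negative Permit negative entries in `counts`. Real binned
#'   counts are non-negative (the default enforces this); synthetic raw
#'   signals built as rates plus additive Gaussian noise may dip below zero
#'   and are stored unfloored to keep the ground-truth additivity exact.
#'
#' @return An object of class `binned_dataset`.
#' @export
#' @examples
#' ds <- binned_dataset(matrix(rpois(40, 2), 20, 2), cbind(rnorm(20), rnorm(20)))
#' ds
binned_dataset <- function(counts, kinematics, bin_width = 0.1,
                           trial_id = NULL, condition_id = NULL,
                           allow_negative = FALSE) {
  counts <- as_matrix2(counts, "counts")
  kinematics <- as_matrix2(kinematics, "kinematics")
  if (any(!is.finite(counts))) stop_invalid("counts must be finite")
  if (!allow_negative && any(counts < 0)) {
    stop_invalid("counts must be non-negative")
  }
  if (nrow(kinematics) != nrow(counts)) {
    stop_invalid("counts and kinematics must have the same number of rows")
  }
  if (ncol(kinematics) != 2L) {
    stop_invalid("kinematics must have two columns (vx, vy)")
  }
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop_invalid("bin_width must be a positive scalar (seconds)")
  }
  n_bins <- nrow(counts)
  if (is.null(trial_id)) trial_id <- rep(1L, n_bins)
  trial_id <- as.integer(trial_id)
  if (length(trial_id) != n_bins) {
    stop_invalid("trial_id must have one entry per time bin")
  }
  # contiguity: each trial label occupies one run
  runs <- rle(trial_id)$values
  if (anyDuplicated(runs[runs != -1L])) {
    stop_invalid("bins of one trial must be contiguous in time")
  }
  trials <- unique(trial_id[trial_id != -1L])
  if (!is.null(condition_id)) {
    condition_id <- as.integer(condition_id)
    if (length(condition_id) != length(trials)) {
      stop_invalid("condition_id must have one entry per trial")
    }
    names(condition_id) <- trials
  }
  structure(
    list(
      counts = counts,
      kinematics = kinematics,
      bin_width = bin_width,
      trial_id = trial_id,
      condition_id = condition_id
    ),
    class = "binned_dataset"
  )
}

#' @export
print.binned_dataset <- function(x, ...) {
  nt <- n_trials(x)
  cat(sprintf(
    "<binned_dataset> %d bins x %d neurons, bin width %g s, %s\n",
    nrow(x$counts), ncol(x$counts), x$bin_width,
    if (nt > 0) sprintf("%d trials", nt) else "untrialed"
  ))
  invisible(x)
}

#' Number of trials in a dataset
#' @param ds A [binned_dataset()].
#' @return Integer trial count (untrialed bins excluded).
#' @export
n_trials <- function(ds) length(trial_ids(ds))

trial_ids <- function(ds) unique(ds$trial_id[ds$trial_id != -1L])

# list of row-index vectors, one per trial, in order of first appearance
trial_rows <- function(ds) {
  ids <- trial_ids(ds)
  lapply(ids, function(i) which(ds$trial_id == i))
}

#' Treat fixed-length contiguous segments as pseudo-trials
#'
#' For recordings without trial markers, folding and trial-level analyses need
#' some trial granularity; contiguous fixed-length segments stand in for
#' trials. Any remainder shorter than `segment_length` is dropped.
#'
#' @param ds A [binned_dataset()].
#' @param segment_length Bins per pseudo-trial (default 10).
#' @return A [binned_dataset()] with synthetic trial ids.
#' @export
as_pseudo_trials <- function(ds, segment_length = 10L) {
  segment_length <- as.integer(segment_length)
  if (segment_length < 1L) stop_invalid("segment_length must be >= 1")
  n_keep <- (nrow(ds$counts) %/% segment_length) * segment_length
  if (n_keep == 0L) stop_invalid("recording shorter than one segment")
  idx <- seq_len(n_keep)
  binned_dataset(
    ds$counts[idx, , drop = FALSE],
    ds$kinematics[idx, , drop = FALSE],
    bin_width = ds$bin_width,
    trial_id = rep(seq_len(n_keep %/% segment_length), each = segment_length),
    allow_negative = TRUE
  )
}

#' Moving-average smoothing of binned counts
#'
#' Centered moving average with shrinking windows at the edges, so a window of
#' `w` bins averages `w` bins in the interior and fewer near trial boundaries.
#' Smoothing never crosses trial boundaries when `trial_id` is supplied.
#'
#' @param counts Time-by-neuron count matrix (or a vector, treated as one
#'   neuron).
#' @param window Odd positive integer; `window = 1` is the identity.
#' @param trial_id Optional per-bin trial labels; smoothing is applied within
#'   each trial independently.
#' @return Matrix of the same shape as `counts`.
#' @export
#' @examples
#' smooth_counts(c(0, 0, 3, 0, 0), window = 3)  # -> 0 1 1 1 0
smooth_counts <- function(counts, window = 3L, trial_id = NULL) {
  counts <- as_matrix2(counts, "counts")
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L || window %% 2L == 0L) {
    stop_invalid("window must be an odd positive integer")
  }
  if (window == 1L) return(counts)
  segs <- if (is.null(trial_id)) {
    list(seq_len(nrow(counts)))
  } else {
    ds_like <- rle(as.integer(trial_id))
    ends <- cumsum(ds_like$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
  }
  if (min(lengths(segs)) < window) {
    stop_invalid("window exceeds the shortest trial (", min(lengths(segs)), " bins)")
  }
  h <- (window - 1L) %/% 2L
  out <- counts
  for (rows in segs) {
    n <- length(rows)
    x <- counts[rows, , drop = FALSE]
    # cumulative-sum trick: mean over [max(1, t-h), min(n, t+h)]
    cs <- rbind(0, apply(x, 2L, cumsum))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    out[rows, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  }
  out
}

#' Smooth the counts of a dataset within trials
#'
#' @param ds A [binned_dataset()].
#' @param window Odd positive integer window, in bins.
#' @return The dataset with smoothed (possibly fractional) counts.
#' @export
smooth_dataset <- function(ds, window = 3L) {
  ds$counts <- smooth_counts(ds$counts, window, trial_id = ds$trial_id)
  ds
}

#' Exclude neurons with low mean firing rate
#'
#' A neuron is kept when its mean count per bin divided by the bin width is at
#' least `min_rate_hz`. Column order of survivors is preserved.
#'
#' @param ds A [binned_dataset()].
#' @param min_rate_hz Minimum mean firing rate in spikes/s (default 0.5 Hz).
#' @return A list with elements `dataset` (the filtered [binned_dataset()])
#'   and `kept` (integer indices of surviving neurons in the input order).
#' @export
filter_low_rate_neurons <- function(ds, min_rate_hz = 0.5) {
  rates <- colMeans(ds$counts) / ds$bin_width
  kept <- which(rates >= min_rate_hz)
  if (length(kept) == 0L) {
    stop_invalid("all neurons fall below ", min_rate_hz, " Hz; empty dataset")
  }
  out <- ds
  out$counts <- ds$counts[, kept, drop = FALSE]
  list(dataset = out, kept = kept)
}

#' Equalize trial lengths
#'
#' Trials shorter than `threshold` bins are discarded; longer trials are
#' truncated to their first `threshold` bins, so every surviving trial has
#' exactly `threshold` bins (as needed for trial-aligned analyses such as the
#' Fano factor).
#'
#' @param ds A [binned_dataset()] with trial structure.
#' @param threshold Target trial length in bins (e.g. 12 or 14).
#' @return A [binned_dataset()] of equal-length trials.
#' @export
enforce_trial_length <- function(ds, threshold) {
  threshold <- as.integer(threshold)
  if (threshold < 1L) stop_invalid("threshold must be >= 1")
  rows_by_trial <- trial_rows(ds)
  ids <- trial_ids(ds)
  keep <- lengths(rows_by_trial) >= threshold
  if (!any(keep)) stop_invalid("no trial reaches ", threshold, " bins")
  rows <- unlist(lapply(rows_by_trial[keep], function(r) r[seq_len(threshold)]))
  kept_ids <- ids[keep]
  cond <- if (!is.null(ds$condition_id)) {
    unname(ds$condition_id[as.character(kept_ids)])
  } else {
    NULL
  }
  binned_dataset(
    ds$counts[rows, , drop = FALSE],
    ds$kinematics[rows, , drop = FALSE],
    bin_width = ds$bin_width,
    trial_id = rep(kept_ids, each = threshold),
    condition_id = cond,
    allow_negative = TRUE
  )
}

#' Trial-level cross-validation folds
#'
#' Whole trials are assigned to `k` near-equal folds by a seeded random
#' permutation followed by contiguous chunking, preventing temporal leakage
#' between train and test bins. The split defines `k` experiments: experiment
#' `i` tests on fold `i`, validates on the next fold (cyclically), and trains
#' on the remaining `k - 2` folds.
#'
#' @param ds A [binned_dataset()] with at least `k` trials.
#' @param k Fold count (default 5).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return An object of class `fold_split` with fields `k`, `trial_ids`,
#'   `fold_of_trial` (named integer vector) and `experiments` (list of
#'   `list(test, validation, train)` fold indices).
#' @export
make_folds <- function(ds, k = 5L, seed = 1L) {
  k <- as.integer(k)
  ids <- trial_ids(ds)
  if (k < 2L || k > length(ids)) {
    stop_invalid("k must be between 2 and the trial count (", length(ids), ")")
  }
  perm <- with_local_seed(seed, sample.int(length(ids)))
  # chunk the permuted trials into k near-equal contiguous blocks
  sizes <- rep(length(ids) %/% k, k) + c(rep(1L, length(ids) %% k),
                                         rep(0L, k - length(ids) %% k))
  fold <- integer(length(ids))
  fold[perm] <- rep(seq_len(k), times = sizes)
  names(fold) <- ids
  experiments <- lapply(seq_len(k), function(i) {
    val <- if (i == k) 1L else i + 1L
    list(test = i, validation = val, train = setdiff(seq_len(k), c(i, val)))
  })
  structure(
    list(k = k, trial_ids = ids, fold_of_trial = fold, experiments = experiments,
         seed = as.integer(seed)),
    class = "fold_split"
  )
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> %d folds over %d trials (seed %d)\n",
              x$k, length(x$trial_ids), x$seed))
  invisible(x)
}

#' Row indices for one cross-validation experiment
#'
#' @param ds The dataset the split was built from.
#' @param split A [make_folds()] result.
#' @param experiment Experiment index in `1..k`.
#' @return List of integer row-index vectors `train`, `validation`, `test`.
#' @export
fold_rows <- function(ds, split, experiment) {
  stopifnot(inherits(split, "fold_split"))
  experiment <- as.integer(experiment)
  if (experiment < 1L || experiment > split$k) {
    stop_invalid("experiment must be in 1..", split$k)
  }
  ex <- split$experiments[[experiment]]
  rows_in_folds <- function(folds) {
    tr <- split$trial_ids[split$fold_of_trial %in% folds]
    which(ds$trial_id %in% tr)
  }
  list(
    train = rows_in_folds(ex$train),
    validation = rows_in_folds(ex$validation),
    test = rows_in_folds(ex$test)
  )
}

#' Raw = relevant + irrelevant signal decomposition
#'
#' The irrelevant part is *defined* as the residual `raw - relevant`, so
#' additivity is exact by construction. The relevant part must be
#' non-negative (it is a firing-rate estimate).
#'
#' @param raw,relevant Time-by-neuron matrices of equal shape.
#' @return An object of class `signal_decomposition` with fields `raw`,
#'   `relevant`, `irrelevant`.
#' @export
signal_decomposition <- function(raw, relevant) {
  raw <- as_matrix2(raw, "raw")
  relevant <- as_matrix2(relevant, "relevant")
  if (!identical(dim(raw), dim(relevant))) {
    stop_invalid("raw and relevant must have identical shape")
  }
  if (any(relevant < 0)) stop_invalid("relevant signals must be non-negative")
  structure(
    list(raw = raw, relevant = relevant, irrelevant = raw - relevant),
    class = "signal_decomposition"
  )
}

#' @export
print.signal_decomposition <- function(x, ...) {
  cat(sprintf("<signal_decomposition> %d bins x %d neurons\n",
              nrow(x$raw), ncol(x$raw)))
  invisible(x)
}
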