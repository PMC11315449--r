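# Post-separation analyses: single-neuron tuning and variability, population
# variance structure, and the decoding analyses that probe how behavioral
# information is distributed across neurons and principal components.

#' Linear (cosine) velocity-tuning fit
#'
#' Ordinary least squares of each neuron's activity on `(1, vx, vy)` — the
#' standard velocity cosine-tuning parameterization. The preferred direction
#' is `atan2(by, bx)`; the per-neuron R-squared measures how much of the
#' activity the affine velocity model explains ("linear tuning R2").
#'
#' @param counts Time-by-neuron activity matrix.
#' @param kinematics `T x 2` velocity matrix.
#' @return A tibble (class `tuning_fit`) with columns `neuron`, `b0`, `bx`,
#'   `by`, `pd_rad`, `r_squared`.
#' @export
cosine_tuning_fit <- function(counts, kinematics) {
  counts <- as_matrix2(counts, "counts")
  V <- kin_matrix(kinematics)
  if (nrow(V) != nrow(counts)) stop_invalid("row counts differ")
  D <- cbind(1, V)
  if (qr(D)$rank < 3L) {
    stop_invalid("constant or collinear kinematics: singular tuning fit")
  }
  fit <- lm.fit(D, counts)
  coefs <- matrix(fit$coefficients, nrow = 3L)
  res <- as.matrix(fit$residuals)
  sst <- colSums(sweep(counts, 2L, colMeans(counts))^2)
  r2 <- ifelse(sst > 0, 1 - colSums(res^2) / sst, 0)
  out <- tibble::tibble(
    neuron = seq_len(ncol(counts)),
    b0 = coefs[1L, ], bx = coefs[2L, ], by = coefs[3L, ],
    pd_rad = atan2(coefs[3L, ], coefs[2L, ]),
    r_squared = unname(r2)
  )
  class(out) <- c("tuning_fit", class(out))
  out
}

#' Preferred-direction deviation between two tuning fits
#'
#' Minimal absolute circular difference between preferred directions, in
#' degrees (range 0 to 180).
#'
#' @param fit_a,fit_b [cosine_tuning_fit()] results over the same neurons.
#' @return Numeric vector of per-neuron angle differences in degrees.
#' @export
pd_angle_difference <- function(fit_a, fit_b) {
  if (nrow(fit_a) != nrow(fit_b)) stop_invalid("neuron counts differ")
  d <- fit_a$pd_rad - fit_b$pd_rad
  abs(((d + pi) %% (2 * pi)) - pi) * 180 / pi
}

#' Fano factor of trial-aligned activity
#'
#' For each neuron and condition: per-bin across-trial variance divided by the
#' across-trial mean, averaged over bins whose mean is nonzero. Trials must be
#' length-equalized first (see [enforce_trial_length()]). Conditions with
#' fewer than two trials are excluded with a warning.
#'
#' @param ds A [binned_dataset()] with equal-length trials; condition labels
#'   default to a single condition.
#' @return A tibble with columns `neuron`, `condition`, `fano`; the
#'   condition-averaged Fano factor per neuron is `attr(, "condition_mean")`.
#' @export
fano_factor <- function(ds) {
  rows_by_trial <- trial_rows(ds)
  len <- unique(lengths(rows_by_trial))
  if (length(len) != 1L) {
    stop_invalid("trials must be length-equalized (enforce_trial_length)")
  }
  ids <- trial_ids(ds)
  cond <- if (!is.null(ds$condition_id)) {
    unname(ds$condition_id[as.character(ids)])
  } else {
    rep(1L, length(ids))
  }
  out <- list()
  for (cc in unique(cond)) {
    tr <- which(cond == cc)
    if (length(tr) < 2L) {
      warning("condition ", cc, " has < 2 trials; excluded")
      next
    }
    for (j in seq_len(ncol(ds$counts))) {
      # trials x bins matrix for neuron j under condition cc
      M <- do.call(rbind, lapply(rows_by_trial[tr], function(r) ds$counts[r, j]))
      mu <- colMeans(M)
      vv <- apply(M, 2L, var)
      keep <- mu != 0
      ff <- if (any(keep)) mean(vv[keep] / mu[keep]) else NA_real_
      out[[length(out) + 1L]] <- tibble::tibble(neuron = j, condition = cc,
                                                fano = ff)
    }
  }
  if (length(out) == 0L) stop_invalid("no condition has >= 2 trials")
  res <- do.call(rbind, out)
  cm <- tapply(res$fano, res$neuron, mean, na.rm = TRUE)
  attr(res, "condition_mean") <- as.numeric(cm)
  res
}

#' Principal-component variance structure
#'
#' Mean-centered PCA of a signal matrix: eigenvalues in descending order,
#' orthonormal axes, cumulative variance fractions, and the dimensionality at
#' a stated cumulative fraction (default 90%, the "primary subspace").
#'
#' @param X Time-by-neuron matrix (at least two rows).
#' @param var_fraction Cumulative-variance level defining the reported
#'   dimensionality (default 0.9).
#' @return An object of class `subspace_report` with `eigenvalues`, `axes`,
#'   `cumulative`, `dim_at`, `var_fraction`, `center`.
#' @export
pca_variance_curve <- function(X, var_fraction = 0.9) {
  X <- as_matrix2(X, "X")
  if (nrow(X) < 2L) stop_invalid("need at least 2 rows")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cumfrac <- cumsum(ev) / sum(ev)
  structure(
    list(eigenvalues = ev, axes = pc$rotation, cumulative = cumfrac,
         dim_at = which(cumfrac >= var_fraction)[1L],
         var_fraction = var_fraction, center = pc$center),
    class = "subspace_report"
  )
}

#' @export
print.subspace_report <- function(x, ...) {
  cat(sprintf("<subspace_report> %d PCs; %d needed for %.0f%% variance\n",
              length(x$eigenvalues), x$dim_at, 100 * x$var_fraction))
  invisible(x)
}

#' Alignment index: percentage variance captured by a subspace
#'
#' `A = Tr(D' C D) / Tr(C) * 100`, with `C` the covariance of `X` and `D` an
#' orthonormal basis of the probing subspace (e.g. the top PCs of another
#' signal). Lies in `[0, 100]`.
#'
#' @param X Signal matrix whose variance is probed.
#' @param D Matrix with orthonormal columns spanning the subspace.
#' @return Percent of the variance of `X` captured by the span of `D`.
#' @export
alignment_index <- function(X, D) {
  X <- as_matrix2(X, "X"); D <- as_matrix2(D, "D")
  if (nrow(D) != ncol(X)) stop_invalid("D rows must match X columns")
  if (max(abs(crossprod(D) - diag(ncol(D)))) > 1e-8) {
    stop_invalid("D must have orthonormal columns")
  }
  C <- stats::cov(X)
  100 * sum(diag(crossprod(D, C %*% D))) / sum(diag(C))
}

#' Variance composition of raw signals
#'
#' Per neuron (or per principal component of the raw signals, when `basis` is
#' supplied): `Var(raw) = Var(relevant) + Var(irrelevant) +
#' 2 Cov(relevant, irrelevant)`. Totals are summed over units. When a basis is
#' supplied, the reported `marker_index` is the last PC at which the relevant
#' variance still meets or exceeds the irrelevant variance.
#'
#' @param dec A [signal_decomposition()].
#' @param basis Optional orthonormal axes (e.g. `pca_variance_curve(raw)$axes`)
#'   onto which all three signals are projected before the per-unit
#'   decomposition.
#' @return An object of class `variance_composition`: a list with `per_unit`
#'   (tibble), `totals` (named vector), `marker_index`, `unit` ("neuron" or
#'   "pc").
#' @export
variance_composition <- function(dec, basis = NULL) {
  stopifnot(inherits(dec, "signal_decomposition"))
  Xr <- dec$relevant; Xi <- dec$irrelevant; Z <- dec$raw
  unit <- "neuron"
  if (!is.null(basis)) {
    basis <- as_matrix2(basis, "basis")
    Xr <- Xr %*% basis; Xi <- Xi %*% basis; Z <- Z %*% basis
    unit <- "pc"
  }
  var_x <- apply(Xr, 2L, var)
  var_y <- apply(Xi, 2L, var)
  var_z <- apply(Z, 2L, var)
  cov2 <- 2 * vapply(seq_len(ncol(Z)), function(j) cov(Xr[, j], Xi[, j]),
                     numeric(1))
  per <- tibble::tibble(
    unit = seq_len(ncol(Z)),
    var_relevant = var_x, var_irrelevant = var_y,
    covariance2 = cov2, var_raw = var_z
  )
  marker <- if (!is.null(basis)) {
    dom <- which(var_x >= var_y)
    if (length(dom)) max(dom) else 0L
  } else {
    NA_integer_
  }
  structure(
    list(per_unit = per,
         totals = c(var_relevant = sum(var_x), var_irrelevant = sum(var_y),
                    covariance2 = sum(cov2), var_raw = sum(var_z)),
         marker_index = marker, unit = unit),
    class = "variance_composition"
  )
}

#' @export
print.variance_composition <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "<variance_composition> per %s; totals: raw %.3g = relevant %.3g + irrelevant %.3g + 2cov %.3g\n",
    x$unit, t["var_raw"], t["var_relevant"], t["var_irrelevant"],
    t["covariance2"]))
  invisible(x)
}

#' Greedy reordering of a neuron correlation matrix
#'
#' Groups neurons for visualization: repeatedly take the neuron on the row of
#' the largest remaining off-diagonal correlation, pull in the
#' `group_size - 1` remaining neurons most correlated with it, and append the
#' group (seed first, then members in descending correlation). The final group
#' may be smaller.
#'
#' @param corr Square symmetric correlation matrix with unit diagonal.
#' @param group_size Neurons per group (default 10).
#' @return An object of class `neuron_ordering`: list with `order` (a
#'   permutation of `1..N`) and `groups` (list of index vectors).
#' @export
reorder_neurons <- function(corr, group_size = 10L) {
  corr <- as_matrix2(corr, "corr")
  if (nrow(corr) != ncol(corr)) stop_invalid("correlation matrix must be square")
  if (max(abs(corr - t(corr))) > 1e-8) stop_invalid("correlation matrix must be symmetric")
  n <- nrow(corr)
  remaining <- seq_len(n)
  groups <- list()
  while (length(remaining) > 0L) {
    if (length(remaining) == 1L) {
      groups[[length(groups) + 1L]] <- remaining
      break
    }
    sub <- corr[remaining, remaining, drop = FALSE]
    diag(sub) <- -Inf
    hits <- which(sub == max(sub), arr.ind = TRUE)
    seed <- remaining[min(hits[, "row"])]   # ties break to the smaller index
    others <- setdiff(remaining, seed)
    sims <- corr[seed, others]
    take <- others[order(sims, decreasing = TRUE)]
    take <- take[seq_len(min(group_size - 1L, length(take)))]
    group <- c(seed, take)
    groups[[length(groups) + 1L]] <- group
    remaining <- setdiff(remaining, group)
  }
  structure(list(order = unlist(groups), groups = groups),
            class = "neuron_ordering")
}

#' @export
print.neuron_ordering <- function(x, ...) {
  cat(sprintf("<neuron_ordering> %d neurons in %d groups\n",
              length(x$order), length(x$groups)))
  invisible(x)
}

#' Decoding as neurons are dropped from strongest to weakest tuning
#'
#' Neurons are removed in descending order of their raw-signal linear tuning
#' R-squared; after each removal the remaining population is decoded
#' (cross-validated) for both raw and relevant signals.
#'
#' @param dec A [signal_decomposition()].
#' @param tuning A [cosine_tuning_fit()] computed on the *raw* signals (fixes
#'   the drop order).
#' @param kinematics `T x 2` velocity matrix.
#' @param split A [make_folds()] split.
#' @param trial_id Per-bin trial labels.
#' @param decoder `"kf"` (default) or `"ann"`.
#' @param max_dropped Largest number of dropped neurons (default `N - 1`).
#' @param seed Seed for the network decoder.
#' @return Tibble with columns `n_dropped`, `signal`, `mean_r2`, `sd_r2`.
#' @export
dropout_curve <- function(dec, tuning, kinematics, split, trial_id,
                          decoder = "kf", max_dropped = NULL, seed = 1L) {
  Y <- kin_matrix(kinematics)
  ord <- order(tuning$r_squared, decreasing = TRUE)
  N <- length(ord)
  max_dropped <- min(max_dropped %||% (N - 1L), N - 1L)
  rows <- list()
  for (nd in 0:max_dropped) {
    keep <- ord[seq.int(nd + 1L, N)]
    for (sig in c("raw", "relevant")) {
      M <- dec[[sig]][, keep, drop = FALSE]
      sc <- cross_validated_decoding(M, Y, split, trial_id, decoder = decoder,
                                     seed = derive_seed(seed, nd), signal = sig)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_dropped = nd, signal = sig, mean_r2 = sc$mean, sd_r2 = sc$sd)
    }
  }
  do.call(rbind, rows)
}

#' Decoding from cumulative principal components
#'
#' PCA is computed on the supplied signals; for each `m`, the signals are
#' projected onto the first `m` PCs in the stated variance order, reconstructed
#' in neuron space, and decoded cross-validated. At `m = N` the projection is
#' lossless, so the score equals full-signal decoding.
#'
#' @param X Signal matrix.
#' @param Y Kinematics.
#' @param split,trial_id Fold split and per-bin trial labels.
#' @param order `"descending"` (largest-variance PCs first) or `"ascending"`.
#' @param decoder `"kf"` or `"ann"`.
#' @param m_values Which PC counts to evaluate (default all `1..N`).
#' @param seed Seed for the network decoder.
#' @return Tibble with columns `m`, `order`, `mean_r2`, `sd_r2`.
#' @export
cumulative_pc_decoding <- function(X, Y, split, trial_id,
                                   order = c("descending", "ascending"),
                                   decoder = "kf", m_values = NULL, seed = 1L) {
  order <- match.arg(order)
  X <- as_matrix2(X, "X")
  rep_ <- pca_variance_curve(X)
  N <- ncol(X)
  axes <- if (order == "descending") rep_$axes else rep_$axes[, N:1, drop = FALSE]
  Xc <- sweep(X, 2L, rep_$center)
  m_values <- m_values %||% seq_len(N)
  rows <- lapply(m_values, function(m) {
    Dm <- axes[, seq_len(m), drop = FALSE]
    Xm <- sweep(Xc %*% Dm %*% t(Dm), 2L, rep_$center, `+`)
    sc <- cross_validated_decoding(Xm, Y, split, trial_id, decoder = decoder,
                                   seed = derive_seed(seed, m))
    tibble::tibble(m = m, order = order, mean_r2 = sc$mean, sd_r2 = sc$sd)
  })
  do.call(rbind, rows)
}

#' Partition signals into primary and secondary subspace components
#'
#' The primary component is the reconstruction from the top PCs capturing
#' `var_fraction` (default 90%) of the variance; the secondary component is
#' the residual, so primary + secondary = signals exactly.
#'
#' @param X Signal matrix.
#' @param var_fraction Cumulative-variance level for the primary subspace.
#' @return List with `primary`, `secondary`, `dim` and the `subspace_report`.
#' @export
pc_partition <- function(X, var_fraction = 0.9) {
  X <- as_matrix2(X, "X")
  rep_ <- pca_variance_curve(X, var_fraction)
  Dm <- rep_$axes[, seq_len(rep_$dim_at), drop = FALSE]
  Xc <- sweep(X, 2L, rep_$center)
  primary <- sweep(Xc %*% Dm %*% t(Dm), 2L, rep_$center, `+`)
  list(primary = primary, secondary = X - primary, dim = rep_$dim_at,
       report = rep_)
}

#' Split samples into lower- and higher-speed regions by error mass
#'
#' Enumerates candidate speed thresholds over `speed_grid`; the threshold is
#' the first grid value at which the cumulative squared decoding error of
#' samples slower than the candidate reaches half the total squared error
#' `Ep`, so the two regions carry (approximately) equal error mass by
#' construction.
#'
#' @param kinematics Observed velocity (`T x 2`).
#' @param predictions Predicted velocity from the primary signals.
#' @param speed_grid Candidate thresholds (default `seq(1, 50, by = 0.1)`).
#' @return An object of class `speed_split`: list with `threshold`,
#'   `low_mask`, `high_mask`, `Ep`, `Ep_low`, `Ep_high`, `per_sample_error`.
#' @export
split_speed_regions <- function(kinematics, predictions,
                                speed_grid = seq(1, 50, by = 0.1)) {
  Y <- kin_matrix(kinematics)
  Y_hat <- as_matrix2(predictions, "predictions")
  if (!identical(dim(Y), dim(Y_hat))) stop_invalid("shape mismatch")
  err <- rowSums((Y - Y_hat)^2)
  speed <- sqrt(rowSums(Y^2))
  Ep <- sum(err)
  threshold <- NA_real_
  for (s in speed_grid) {
    if (sum(err[speed < s]) >= 0.5 * Ep) { threshold <- s; break }
  }
  if (is.na(threshold)) {
    stop_invalid("no grid speed reaches half the error mass; extend speed_grid")
  }
  low <- speed <= threshold
  structure(
    list(threshold = threshold, low_mask = low, high_mask = !low,
         Ep = Ep, Ep_low = sum(err[low]), Ep_high = sum(err[!low]),
         per_sample_error = err),
    class = "speed_split"
  )
}

#' @export
print.speed_split <- function(x, ...) {
  cat(sprintf("<speed_split> threshold %.1f; Ep_low/Ep = %.3f (%d low, %d high)\n",
              x$threshold, x$Ep_low / x$Ep, sum(x$low_mask), sum(x$high_mask)))
  invisible(x)
}

#' Absolute and relative improvement ratios after superimposing secondary
#' signals
#'
#' Given the speed split computed from primary-signal predictions and the
#' per-sample squared errors after superimposing the secondary signals,
#' computes `AIR = -(E_after - E_before) / E_before` per region and the
#' per-sample `RIR_i = -(e_after_i - e_i) / e_i` (samples with zero baseline
#' error are excluded; their count is reported).
#'
#' @param split A [split_speed_regions()] result.
#' @param error_superimposed Per-sample squared errors of the
#'   primary+secondary predictions (same length as `split$per_sample_error`).
#' @return An object of class `speed_improvement_report`: list with
#'   `air_low`, `air_high`, `rir` (tibble of per-sample values with region),
#'   `n_zero_excluded`, and the error totals.
#' @export
improvement_ratios <- function(split, error_superimposed) {
  stopifnot(inherits(split, "speed_split"))
  eps_ <- as.numeric(error_superimposed)
  ep <- split$per_sample_error
  if (length(eps_) != length(ep)) stop_invalid("error vector lengths differ")
  if (any(eps_ < 0)) stop_invalid("squared errors must be non-negative")
  Eps_low <- sum(eps_[split$low_mask])
  Eps_high <- sum(eps_[split$high_mask])
  nonzero <- ep > 0
  rir <- tibble::tibble(
    sample = which(nonzero),
    region = ifelse(split$low_mask[nonzero], "low", "high"),
    rir = -(eps_[nonzero] - ep[nonzero]) / ep[nonzero]
  )
  structure(
    list(
      threshold = split$threshold,
      Ep = split$Ep, Ep_low = split$Ep_low, Ep_high = split$Ep_high,
      Eps_low = Eps_low, Eps_high = Eps_high,
      air_low = -(Eps_low - split$Ep_low) / split$Ep_low,
      air_high = -(Eps_high - split$Ep_high) / split$Ep_high,
      rir = rir,
      n_zero_excluded = sum(!nonzero)
    ),
    class = "speed_improvement_report"
  )
}

#' @export
print.speed_improvement_report <- function(x, ...) {
  cat(sprintf("<speed_improvement_report> AIR low %.3f, high %.3f (threshold %.1f)\n",
              x$air_low, x$air_high, x$threshold))
  invisible(x)
}
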