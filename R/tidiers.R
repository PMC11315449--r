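# broom-style accessors for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.decoding_scores <- function(x, ...) {
  tibble::tibble(experiment = x$scores$experiment, r2 = x$scores$r2,
                 decoder = x$decoder, signal = x$signal)
}

#' @export
glance.decoding_scores <- function(x, ...) {
  tibble::tibble(mean_r2 = x$mean, sd_r2 = x$sd, n_folds = nrow(x$scores),
                 decoder = x$decoder, signal = x$signal)
}

#' @export
tidy.variance_composition <- function(x, ...) x$per_unit

#' @export
glance.variance_composition <- function(x, ...) {
  t <- as.list(x$totals)
  tibble::tibble(var_raw = t$var_raw, var_relevant = t$var_relevant,
                 var_irrelevant = t$var_irrelevant,
                 covariance2 = t$covariance2, unit = x$unit,
                 marker_index = x$marker_index)
}

#' @export
tidy.subspace_report <- function(x, ...) {
  tibble::tibble(pc = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
                 cumulative_fraction = x$cumulative)
}

#' @export
glance.subspace_report <- function(x, ...) {
  tibble::tibble(n_pcs = length(x$eigenvalues), dim_at = x$dim_at,
                 var_fraction = x$var_fraction)
}

#' @export
tidy.speed_improvement_report <- function(x, ...) x$rir

#' @export
glance.speed_improvement_report <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, air_low = x$air_low,
                 air_high = x$air_high, Ep = x$Ep,
                 n_zero_excluded = x$n_zero_excluded)
}

#' @export
glance.dvae_model <- function(x, ...) {
  tibble::tibble(n_neurons = x$n_neurons, latent_dim = x$config$latent_dim,
                 alpha = x$config$alpha, beta = x$config$beta,
                 trained = isTRUE(attr(x, "trained")))
}
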