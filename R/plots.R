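# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   geom_col labs theme_minimal facet_wrap scale_x_continuous .data
#' @export
ggplot2::autoplot

#' @export
autoplot.tuning_fit <- function(object, ...) {
  ggplot(object, aes(x = pd_rad * 180 / pi, y = r_squared)) +
    geom_point() +
    labs(x = "preferred direction (deg)", y = expression("linear tuning" ~ R^2),
         title = "Cosine tuning across the population") +
    theme_minimal()
}

#' @export
autoplot.alpha_sweep <- function(object, ...) {
  df <- tibble::tibble(
    alpha = rep(object$alpha, 3L),
    value = c(object$d_re, object$d_ir, object$criterion),
    what = rep(c("Dre (relevant)", "Dir (irrelevant)", "criterion"),
               each = nrow(object))
  )
  ggplot(df, aes(x = alpha, y = value, colour = what)) +
    geom_line() + geom_point() +
    labs(x = expression(alpha), y = "validation R2 / criterion",
         colour = NULL, title = "Distillation-weight sweep") +
    theme_minimal()
}

#' @export
autoplot.subspace_report <- function(object, ...) {
  ggplot(tidy(object), aes(x = pc, y = cumulative_fraction)) +
    geom_line() + geom_point() +
    labs(x = "principal components", y = "cumulative variance fraction",
         title = sprintf("%d PCs reach %.0f%% variance", object$dim_at,
                         100 * object$var_fraction)) +
    theme_minimal()
}

#' @export
autoplot.variance_composition <- function(object, ...) {
  per <- object$per_unit
  df <- tibble::tibble(
    unit = rep(per$unit, 3L),
    component = rep(c("relevant", "irrelevant", "2 cov"), each = nrow(per)),
    variance = c(per$var_relevant, per$var_irrelevant, per$covariance2)
  )
  ggplot(df, aes(x = unit, y = variance, fill = component)) +
    geom_col() +
    labs(x = object$unit, y = "variance",
         title = "Variance composition of raw signals") +
    theme_minimal()
}

#' Plot trial-averaged training trace of a d-VAE fit
#'
#' @param trace The `trace` tibble returned by [train_dvae()].
#' @return A ggplot object with train/validation total loss per epoch.
#' @export
plot_training_trace <- function(trace) {
  df <- tibble::tibble(
    epoch = rep(trace$epoch, 2L),
    loss = c(trace$total, trace$val_total),
    set = rep(c("train", "validation"), each = nrow(trace))
  )
  ggplot(df, aes(x = epoch, y = loss, colour = set)) +
    geom_line() +
    labs(x = "epoch", y = "total loss", colour = NULL,
         title = "d-VAE training") +
    theme_minimal()
}

#' Plot a dropout or cumulative-PC decoding curve
#'
#' @param curve Tibble from [dropout_curve()] or [cumulative_pc_decoding()].
#' @return A ggplot object.
#' @export
plot_decoding_curve <- function(curve) {
  xvar <- if ("n_dropped" %in% names(curve)) "n_dropped" else "m"
  p <- ggplot(curve, aes(x = .data[[xvar]], y = .data$mean_r2))
  if ("signal" %in% names(curve)) {
    p <- p + aes(colour = .data$signal)
  }
  p + geom_line() + geom_point() +
    labs(x = if (xvar == "n_dropped") "neurons dropped (strongest tuning first)"
         else "principal components included",
         y = "decoding R2") +
    theme_minimal()
}
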