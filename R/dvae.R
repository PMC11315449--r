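# The distillation VAE. Four networks act on single time bins:
#   f : counts -> (mu, log sigma^2)     inference (encoder)
#   g : latent -> rates                 generation (decoder, softplus output)
#   m : kinematics -> (mu_p, log s2_p)  behavior-conditioned learned prior
#   h : latent mean -> kinematics       affine readout
# trained end-to-end under  L = Lrec + beta * LKL + alpha * Ldec  where
# Lrec is the Poisson negative log likelihood of the raw counts given the
# generated rates, LKL aligns the learned prior with the posterior, and
# Ldec averages two decoding MSEs: readout from the posterior mean of the
# raw counts (Ldec1) and from the posterior mean of the *generated* signals
# re-encoded through the same f and h (Ldec2).

#' d-VAE configuration
#'
#' @param latent_dim Latent dimensionality `d` (default 50).
#' @param alpha Decoding-loss weight; governs the reconstruction/decoding
#'   trade-off that defines "behaviorally relevant". Default 0.9 (the value
#'   selected for synthetic data by the decoding-based criterion; real
#'   recordings typically select values in 0.1--0.9).
#' @param beta KL weight (default 0.001).
#' @param encoder_widths Hidden widths of the inference network `f`
#'   (default `c(300, 100)`); the generator `g` is symmetric.
#' @param prior_width Hidden width of the prior network `m` (default 300).
#' @param lr Adam step size (default 1e-3).
#' @param batch_size Minibatch size in time bins (default 256).
#' @param max_epochs Epoch budget (default 500; early stopping usually
#'   terminates much sooner).
#' @param patience,rel_tol Early stopping: stop when the validation total loss
#'   has not improved on the best by `rel_tol` (relative, default 1%) within
#'   `patience` epochs (default 10).
#' @param kl_direction `"prior_posterior"` (default) computes
#'   `KL(p_m(z|y) || q_f(z|x))`; `"posterior_prior"` the conventional reverse.
#' @param grad_clip Global gradient-norm clip (default 5).
#' @param seed Integer seed making training deterministic.
#' @return An object of class `dvae_config`.
#' @export
dvae_config <- function(latent_dim = 50L, alpha = 0.9, beta = 0.001,
                        encoder_widths = c(300L, 100L), prior_width = 300L,
                        lr = 1e-3, batch_size = 256L, max_epochs = 500L,
                        patience = 10L, rel_tol = 0.01,
                        kl_direction = c("prior_posterior", "posterior_prior"),
                        grad_clip = 5, seed = 1L) {
  kl_direction <- match.arg(kl_direction)
  latent_dim <- as.integer(latent_dim)
  if (latent_dim < 1L) stop_invalid("latent_dim must be >= 1")
  if (alpha < 0) stop_invalid("alpha must be >= 0")
  if (beta < 0) stop_invalid("beta must be >= 0")
  if (patience < 1L) stop_invalid("patience must be >= 1")
  structure(
    list(latent_dim = latent_dim, alpha = alpha, beta = beta,
         encoder_widths = as.integer(encoder_widths),
         prior_width = as.integer(prior_width), lr = lr,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         rel_tol = rel_tol, kl_direction = kl_direction,
         grad_clip = grad_clip, seed = as.integer(seed)),
    class = "dvae_config"
  )
}

#' @export
print.dvae_config <- function(x, ...) {
  cat(sprintf("<dvae_config> d=%d, alpha=%g, beta=%g, f widths (%s), KL %s\n",
              x$latent_dim, x$alpha, x$beta,
              paste(x$encoder_widths, collapse = ", "), x$kl_direction))
  invisible(x)
}

#' Initialize a d-VAE model
#'
#' @param n_neurons Number of observed neurons.
#' @param config A [dvae_config()].
#' @param seed Seed for weight initialization (defaults to `config$seed`).
#' @return An object of class `dvae_model` (untrained).
#' @export
dvae_init <- function(n_neurons, config = dvae_config(), seed = config$seed) {
  n <- as.integer(n_neurons)
  d <- config$latent_dim
  w <- config$encoder_widths
  with_local_seed(seed, {
    structure(
      list(
        n_neurons = n,
        config = config,
        f_trunk = mlp_init(c(n, w), out_act = "relu"),
        f_mu = init_linear(w[length(w)], d),
        f_lv = init_linear(w[length(w)], d),
        g = mlp_init(c(d, rev(w), n), out_act = "softplus"),
        m_trunk = mlp_init(c(2L, config$prior_width), out_act = "relu"),
        m_mu = init_linear(config$prior_width, d),
        m_lv = init_linear(config$prior_width, d),
        h = init_linear(d, 2L),
        # kinematics standardization (set from the training folds by
        # train_dvae); the readout h and prior m operate on z-scored
        # velocities so the decoding loss is commensurate with Lrec
        # regardless of velocity units
        y_center = c(0, 0),
        y_scale = c(1, 1)
      ),
      class = "dvae_model"
    )
  })
}

#' @export
print.dvae_model <- function(x, ...) {
  cat(sprintf("<dvae_model> %d neurons -> d=%d latent (alpha=%g, beta=%g)%s\n",
              x$n_neurons, x$config$latent_dim, x$config$alpha, x$config$beta,
              if (isTRUE(attr(x, "trained"))) ", trained" else ""))
  invisible(x)
}

dvae_param_list <- function(model) {
  list(f_trunk = model$f_trunk$layers, f_mu = model$f_mu, f_lv = model$f_lv,
       g = model$g$layers, m_trunk = model$m_trunk$layers,
       m_mu = model$m_mu, m_lv = model$m_lv, h = model$h)
}

dvae_set_params <- function(model, plist) {
  model$f_trunk$layers <- plist$f_trunk
  model$f_mu <- plist$f_mu
  model$f_lv <- plist$f_lv
  model$g$layers <- plist$g
  model$m_trunk$layers <- plist$m_trunk
  model$m_mu <- plist$m_mu
  model$m_lv <- plist$m_lv
  model$h <- plist$h
  model
}

#' Posterior over latent representations
#'
#' Runs the inference network `f` on a batch of raw signals.
#'
#' @param model A [dvae_init()] / [train_dvae()] model.
#' @param x Batch matrix, bins by neurons.
#' @return An object of class `latent_posterior` with matrices `mu` and
#'   `log_var` (bins by latent dim).
#' @export
infer_posterior <- function(model, x) {
  x <- as_matrix2(x, "x")
  if (ncol(x) != model$n_neurons) {
    stop_invalid("x has ", ncol(x), " columns; model expects ", model$n_neurons)
  }
  H <- mlp_fwd(model$f_trunk, x)
  structure(
    list(mu = linear_fwd(model$f_mu, H), log_var = linear_fwd(model$f_lv, H)),
    class = "latent_posterior"
  )
}

#' Reparameterization trick
#'
#' `z = mu + sigma * eps` elementwise, with `sigma = exp(log_var / 2)`.
#'
#' @param post A [infer_posterior()] result (or a list with `mu`, `log_var`).
#' @param eps Standard-normal draw of the same shape as `post$mu`; drawn
#'   internally when omitted.
#' @return Latent batch matrix.
#' @export
reparameterize <- function(post, eps = NULL) {
  mu <- as_matrix2(post$mu, "mu")
  lv <- as_matrix2(post$log_var, "log_var")
  if (is.null(eps)) eps <- matrix(rnorm(length(mu)), nrow(mu))
  eps <- as_matrix2(eps, "eps")
  if (!identical(dim(eps), dim(mu))) stop_invalid("eps shape must match mu")
  mu + exp(0.5 * lv) * eps
}

#' Poisson negative log likelihood reconstruction loss
#'
#' Mean over all entries of `rate - target * log(rate)`; the `log(target!)`
#' constant is dropped (it does not affect optimization) so the loss stays
#' defined for the fractional counts produced by smoothing. Rates are floored
#' at `floor` before the log.
#'
#' @param rate Positive matrix of predicted rates.
#' @param target Count matrix of the same shape.
#' @param floor Numerical floor applied to `rate` (default 1e-8).
#' @param check_targets Error on negative targets (default TRUE). Synthetic
#'   raw signals built as rates plus Gaussian noise may be negative; the
#'   training loop disables the check for them, since the continuous form of
#'   the loss remains well defined.
#' @return Scalar loss, minimized at `rate = target`.
#' @export
#' @examples
#' poisson_nll(matrix(1, 2, 2), matrix(1, 2, 2))  # = 1
poisson_nll <- function(rate, target, floor = 1e-8, check_targets = TRUE) {
  rate <- as_matrix2(rate, "rate")
  target <- as_matrix2(target, "target")
  if (!identical(dim(rate), dim(target))) {
    stop_invalid("rate and target must have identical shape")
  }
  if (check_targets && any(target < 0)) {
    stop_invalid("negative targets are not valid counts")
  }
  r <- pmax(rate, floor)
  mean(r - target * log(r))
}

#' Diagonal-Gaussian Kullback-Leibler divergence
#'
#' Closed form `KL(p || q)` between diagonal Gaussians, summed over latent
#' dimensions and averaged over the batch. The default argument order matches
#' the model's alignment term: `p` is the learned prior `m(y)` and `q` the
#' posterior `f(x)`.
#'
#' @param mu_p,var_p Mean and variance of `p` (matrices or vectors).
#' @param mu_q,var_q Mean and variance of `q`.
#' @return Scalar KL divergence (non-negative).
#' @export
gaussian_kl <- function(mu_p, var_p, mu_q, var_q) {
  mu_p <- as_matrix2(mu_p, "mu_p"); var_p <- as_matrix2(var_p, "var_p")
  mu_q <- as_matrix2(mu_q, "mu_q"); var_q <- as_matrix2(var_q, "var_q")
  if (any(var_p <= 0) || any(var_q <= 0)) {
    stop_invalid("variances must be strictly positive")
  }
  per <- 0.5 * (log(var_q / var_p) + (var_p + (mu_p - mu_q)^2) / var_q - 1)
  mean(rowSums(per))
}

#' The two decoding losses and their combination
#'
#' `Ldec1 = MSE(h(mu), y)` with `mu` the posterior mean of the raw signals;
#' `Ldec2 = MSE(h(mu_r), y)` with `mu_r` the posterior mean of the generated
#' relevant signals `x_r = g(z)`, `z` reparameterized from the posterior. The
#' same `f` and `h` weights serve both paths;
#' `Ldec = (Ldec1 + Ldec2) / 2`.
#'
#' @param model A `dvae_model`.
#' @param x,y Paired batch of raw signals and kinematics.
#' @param eps Optional fixed standard-normal draw for the reparameterization.
#' @return List with `ldec1`, `ldec2`, `ldec`.
#' @export
decoding_losses <- function(model, x, y, eps = NULL) {
  y <- scale_kinematics(model, as_matrix2(y, "y"))
  post <- infer_posterior(model, x)
  ldec1 <- mean((linear_fwd(model$h, post$mu) - y)^2)
  z <- reparameterize(post, eps)
  xr <- mlp_fwd(model$g, z)
  post_r <- infer_posterior(model, xr)
  ldec2 <- mean((linear_fwd(model$h, post_r$mu) - y)^2)
  list(ldec1 = ldec1, ldec2 = ldec2, ldec = (ldec1 + ldec2) / 2)
}

#' Total training loss
#'
#' `L = Lrec + beta * LKL + alpha * Ldec`.
#'
#' @param lrec,lkl,ldec Loss components.
#' @param config A [dvae_config()] carrying `alpha` and `beta`.
#' @return Scalar total loss.
#' @export
total_loss <- function(lrec, lkl, ldec, config) {
  stopifnot(is.finite(lrec), is.finite(lkl), is.finite(ldec))
  lrec + config$beta * lkl + config$alpha * ldec
}

# Forward pass + total loss + analytic gradients for one batch.
# Returns losses and the gradient list aligned with dvae_param_list().
dvae_batch_grad <- function(model, X, Y, eps) {
  cfg <- model$config
  B <- nrow(X)
  d <- cfg$latent_dim

  # ---- forward ----
  tf <- mlp_fwd(model$f_trunk, X, cache = TRUE)
  mu <- linear_fwd(model$f_mu, tf$out)
  lv <- linear_fwd(model$f_lv, tf$out)
  sd_ <- exp(0.5 * lv)
  z <- mu + sd_ * eps
  tg <- mlp_fwd(model$g, z, cache = TRUE)
  xr <- tg$out
  floor_ <- 1e-8
  rate <- pmax(xr, floor_)
  lrec <- mean(rate - X * log(rate))

  tf2 <- mlp_fwd(model$f_trunk, xr, cache = TRUE)
  mur <- linear_fwd(model$f_mu, tf2$out)
  p1 <- linear_fwd(model$h, mu)
  p2 <- linear_fwd(model$h, mur)
  ldec1 <- mean((p1 - Y)^2)
  ldec2 <- mean((p2 - Y)^2)
  ldec <- (ldec1 + ldec2) / 2

  tm <- mlp_fwd(model$m_trunk, Y, cache = TRUE)
  mup <- linear_fwd(model$m_mu, tm$out)
  lvp <- linear_fwd(model$m_lv, tm$out)
  vp <- exp(lvp); vq <- exp(lv)
  if (cfg$kl_direction == "prior_posterior") {
    lkl <- mean(rowSums(0.5 * (lv - lvp + (vp + (mup - mu)^2) / vq - 1)))
  } else {
    lkl <- mean(rowSums(0.5 * (lvp - lv + (vq + (mu - mup)^2) / vp - 1)))
  }
  total <- lrec + cfg$beta * lkl + cfg$alpha * ldec

  # ---- backward ----
  w_dec <- cfg$alpha * 0.5
  dP1 <- w_dec * 2 * (p1 - Y) / length(p1)
  dP2 <- w_dec * 2 * (p2 - Y) / length(p2)

  gh1 <- linear_bwd(model$h, mu, dP1)
  gh2 <- linear_bwd(model$h, mur, dP2)
  g_h <- list(W = gh1$dW + gh2$dW, b = gh1$db + gh2$db)

  # Ldec2 path back through f (second pass) into xr
  gmu2 <- linear_bwd(model$f_mu, tf2$out, gh2$dX)
  back2 <- mlp_bwd(model$f_trunk, tf2, gmu2$dX)
  dxr_dec2 <- back2$dX

  # Lrec gradient wrt xr (zero where the floor binds)
  dxr_rec <- (1 - X / rate) / length(rate)
  dxr_rec[xr < floor_] <- 0
  dxr <- dxr_rec + dxr_dec2

  backg <- mlp_bwd(model$g, tg, dxr)
  dz <- backg$dX

  # KL gradients
  w <- 0.5 / B
  if (cfg$kl_direction == "prior_posterior") {
    dmu_kl <- w * 2 * (mu - mup) / vq
    dlv_kl <- w * (1 - (vp + (mup - mu)^2) / vq)
    dmup_kl <- w * 2 * (mup - mu) / vq
    dlvp_kl <- w * (vp / vq - 1)
  } else {
    dmu_kl <- w * 2 * (mu - mup) / vp
    dlv_kl <- w * (vq / vp - 1)
    dmup_kl <- w * 2 * (mup - mu) / vp
    dlvp_kl <- w * (1 - (vq + (mu - mup)^2) / vp)
  }

  dmu <- dz + gh1$dX + cfg$beta * dmu_kl
  dlv <- dz * eps * 0.5 * sd_ + cfg$beta * dlv_kl

  gmu <- linear_bwd(model$f_mu, tf$out, dmu)
  glv <- linear_bwd(model$f_lv, tf$out, dlv)
  back1 <- mlp_bwd(model$f_trunk, tf, gmu$dX + glv$dX)

  g_f_trunk <- Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                   back1$grads, back2$grads)
  g_f_mu <- list(W = gmu$dW + gmu2$dW, b = gmu$db + gmu2$db)

  dmup <- cfg$beta * dmup_kl
  dlvp <- cfg$beta * dlvp_kl
  gmup <- linear_bwd(model$m_mu, tm$out, dmup)
  glvp <- linear_bwd(model$m_lv, tm$out, dlvp)
  backm <- mlp_bwd(model$m_trunk, tm, gmup$dX + glvp$dX)

  grads <- list(
    f_trunk = g_f_trunk,
    f_mu = list(W = g_f_mu$W, b = g_f_mu$b),
    f_lv = list(W = glv$dW, b = glv$db),
    g = backg$grads,
    m_trunk = backm$grads,
    m_mu = list(W = gmup$dW, b = gmup$db),
    m_lv = list(W = glvp$dW, b = glvp$db),
    h = list(W = g_h$W, b = g_h$b)
  )
  list(losses = c(lrec = lrec, lkl = lkl, ldec1 = ldec1, ldec2 = ldec2,
                  ldec = ldec, total = total),
       grads = grads)
}

# loss components without gradients (for validation)
dvae_eval_losses <- function(model, X, Y, eps) {
  cfg <- model$config
  post <- infer_posterior(model, X)
  z <- post$mu + exp(0.5 * post$log_var) * eps
  xr <- mlp_fwd(model$g, z)
  lrec <- poisson_nll(xr, X, check_targets = FALSE)
  mur <- infer_posterior(model, xr)$mu
  ldec1 <- mean((linear_fwd(model$h, post$mu) - Y)^2)
  ldec2 <- mean((linear_fwd(model$h, mur) - Y)^2)
  ldec <- (ldec1 + ldec2) / 2
  Hm <- mlp_fwd(model$m_trunk, Y)
  mup <- linear_fwd(model$m_mu, Hm)
  vp <- exp(linear_fwd(model$m_lv, Hm))
  vq <- exp(post$log_var)
  lkl <- if (cfg$kl_direction == "prior_posterior") {
    gaussian_kl(mup, vp, post$mu, vq)
  } else {
    gaussian_kl(post$mu, vq, mup, vp)
  }
  c(lrec = lrec, lkl = lkl, ldec1 = ldec1, ldec2 = ldec2, ldec = ldec,
    total = lrec + cfg$beta * lkl + cfg$alpha * ldec)
}

#' Train a d-VAE on one cross-validation experiment
#'
#' Minibatches are single time bins, shuffled within the training folds each
#' epoch. The checkpoint with the best validation *total* loss is returned;
#' training stops early when the validation loss has not improved on the best
#' by `rel_tol` within `patience` epochs. Deterministic given `config$seed`.
#'
#' @param ds A [binned_dataset()].
#' @param split A [make_folds()] split (omit to train on all bins with a
#'   random 20% validation subset).
#' @param experiment Experiment index within the split (default 1).
#' @param config A [dvae_config()].
#' @return List with `model` (class `dvae_model`, best checkpoint) and `trace`
#'   (a tibble of per-epoch loss components on train and validation, plus
#'   attributes `best_epoch` and `stop_epoch`).
#' @export
train_dvae <- function(ds, split = NULL, experiment = 1L,
                       config = dvae_config()) {
  X_all <- ds$counts
  Y_all <- ds$kinematics
  if (!is.null(split)) {
    rows <- fold_rows(ds, split, experiment)
    tr <- rows$train; va <- rows$validation
  } else {
    n <- nrow(X_all)
    va <- with_local_seed(derive_seed(config$seed, 17L),
                          sample.int(n, max(1L, round(0.2 * n))))
    tr <- setdiff(seq_len(n), va)
  }
  model <- dvae_init(ncol(X_all), config)
  # standardize velocities with training-fold statistics (units absorbed;
  # see dvae_init); constant dimensions keep scale 1
  model$y_center <- colMeans(Y_all[tr, , drop = FALSE])
  ysc <- apply(Y_all[tr, , drop = FALSE], 2L, sd)
  model$y_scale <- ifelse(ysc > 1e-12, ysc, 1)
  Y_all <- scale_kinematics(model, Y_all)
  trace_rows <- list()
  if (config$max_epochs == 0L) {
    attr(model, "trained") <- FALSE
    tr_tbl <- empty_trace()
    return(list(model = model, trace = tr_tbl))
  }
  d <- config$latent_dim
  Xtr <- X_all[tr, , drop = FALSE]; Ytr <- Y_all[tr, , drop = FALSE]
  Xva <- X_all[va, , drop = FALSE]; Yva <- Y_all[va, , drop = FALSE]

  with_local_seed(derive_seed(config$seed, 23L), {
    flat <- flatten_params(dvae_param_list(model))
    opt <- adam_init(flat)
    es <- es_init("min", rel_tol = config$rel_tol, patience = config$patience)
    best_flat <- flat
    eps_va <- matrix(rnorm(nrow(Xva) * d), nrow(Xva))
    for (epoch in seq_len(config$max_epochs)) {
      order <- sample.int(nrow(Xtr))
      ep_losses <- NULL; nb <- 0L
      for (start in seq(1L, length(order), by = config$batch_size)) {
        idx <- order[start:min(start + config$batch_size - 1L, length(order))]
        eps <- matrix(rnorm(length(idx) * d), length(idx))
        bg <- dvae_batch_grad(model, Xtr[idx, , drop = FALSE],
                              Ytr[idx, , drop = FALSE], eps)
        if (!all(is.finite(bg$losses))) {
          stop_invalid("non-finite d-VAE loss at epoch ", epoch, ", batch ",
                       nb + 1L, " (", paste(names(bg$losses), "=",
                                            signif(bg$losses, 4),
                                            collapse = ", "), ")")
        }
        step <- adam_step(flat, flatten_params(bg$grads), opt,
                          lr = config$lr, clip = config$grad_clip)
        flat <- step$params; opt <- step$state
        model <- dvae_set_params(model, assign_params(dvae_param_list(model), flat))
        ep_losses <- if (is.null(ep_losses)) bg$losses else ep_losses + bg$losses
        nb <- nb + 1L
      }
      val <- dvae_eval_losses(model, Xva, Yva, eps_va)
      if (!all(is.finite(val))) {
        stop_invalid("non-finite validation loss at epoch ", epoch)
      }
      trace_rows[[epoch]] <- c(epoch = epoch, ep_losses / nb,
                               stats::setNames(val, paste0("val_", names(val))))
      es <- es_update(es, val[["total"]], epoch)
      if (es$is_new_best) best_flat <- flat
      if (es$stop) break
    }
    model <- dvae_set_params(model, assign_params(dvae_param_list(model), best_flat))
  })
  attr(model, "trained") <- TRUE
  trace <- tibble::as_tibble(as.data.frame(do.call(rbind, trace_rows)))
  attr(trace, "best_epoch") <- es_best_epoch(trace)
  attr(trace, "stop_epoch") <- nrow(trace)
  list(model = model, trace = trace)
}

empty_trace <- function() {
  tibble::tibble(epoch = integer(), lrec = numeric(), lkl = numeric(),
                 ldec1 = numeric(), ldec2 = numeric(), ldec = numeric(),
                 total = numeric(), val_lrec = numeric(), val_lkl = numeric(),
                 val_ldec1 = numeric(), val_ldec2 = numeric(),
                 val_ldec = numeric(), val_total = numeric())
}

es_best_epoch <- function(trace) {
  if (nrow(trace) == 0L) return(0L)
  which.min(trace$val_total)
}

#' Distill raw signals into relevant and irrelevant components
#'
#' Feeds the raw signals through the inference network and generates relevant
#' signals from the posterior *mean* (no sampling at test time, so the
#' decomposition is deterministic); the irrelevant component is the residual.
#'
#' @param model A trained `dvae_model`.
#' @param ds A [binned_dataset()] (or a bare count matrix).
#' @return A [signal_decomposition()].
#' @export
distill <- function(model, ds) {
  X <- if (inherits(ds, "binned_dataset")) ds$counts else as_matrix2(ds, "ds")
  post <- infer_posterior(model, X)
  relevant <- mlp_fwd(model$g, post$mu)
  signal_decomposition(X, relevant)
}

#' Generate relevant signals from kinematics through the learned prior
#'
#' The auxiliary encoding-model path: kinematics -> prior mean -> generator.
#' Useful for inspecting what the model has learned about neural encoding;
#' not used in distillation.
#'
#' @param model A trained `dvae_model`.
#' @param kinematics `T x 2` velocity matrix.
#' @return `T x N` matrix of generated rates.
#' @export
generate_from_kinematics <- function(model, kinematics) {
  Y <- scale_kinematics(model, kin_matrix(kinematics))
  Hm <- mlp_fwd(model$m_trunk, Y)
  mlp_fwd(model$g, linear_fwd(model$m_mu, Hm))
}

scale_kinematics <- function(model, Y) {
  sweep(sweep(Y, 2L, model$y_center %||% c(0, 0)), 2L,
        model$y_scale %||% c(1, 1), `/`)
}

# cheap structural fingerprint of a dataset, stored in checkpoints
data_fingerprint <- function(ds) {
  X <- if (inherits(ds, "binned_dataset")) ds$counts else as_matrix2(ds, "ds")
  sprintf("%dx%d:%.10e:%.10e", nrow(X), ncol(X), sum(X), sum(X^2))
}

#' Save / load a d-VAE checkpoint
#'
#' The checkpoint is a single file holding the weights, the configuration, the
#' training seed, and a fingerprint of the training data; loading against a
#' dataset verifies the fingerprint.
#'
#' @param model A `dvae_model`.
#' @param path File path.
#' @param ds Optional dataset whose fingerprint is stored / verified.
#' @return `save_dvae` returns `path` invisibly; `load_dvae` the model.
#' @export
save_dvae <- function(model, path, ds = NULL) {
  obj <- list(model = model, config = model$config, seed = model$config$seed,
              fingerprint = if (!is.null(ds)) data_fingerprint(ds) else NULL)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_dvae
#' @export
load_dvae <- function(path, ds = NULL) {
  obj <- readRDS(path)
  if (!is.null(ds) && !is.null(obj$fingerprint) &&
      !identical(obj$fingerprint, data_fingerprint(ds))) {
    stop_invalid("checkpoint fingerprint does not match the supplied dataset")
  }
  obj$model
}
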