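# Reference decoders used for every decoding claim: a velocity Kalman filter
# fitted by least squares and a feed-forward network regressor, plus the
# cross-validated R-squared harness.

#' Fit Kalman-filter parameters by least squares
#'
#' State is 2-D velocity augmented with a constant-1 bias component (to absorb
#' baseline firing). The state-transition matrix `A` is the least-squares
#' regression of the next state on the current state (within trials, so no
#' transition crosses a trial boundary), the observation matrix `C` the
#' least-squares regression of neural signals on the state, and `Q`, `R` the
#' corresponding residual covariances (`R` ridge-regularized for
#' invertibility).
#'
#' @param X Neural matrix, bins by neurons.
#' @param Y Kinematics, bins by 2.
#' @param trial_id Optional per-bin trial labels; transitions are only taken
#'   within trials.
#' @param ridge Diagonal ridge added to `R` (default 1e-6).
#' @param add_bias Augment the state with a constant 1 (default TRUE).
#' @return An object of class `kf_params` with `A`, `C`, `Q`, `R`, `x0`, `P0`.
#' @export
fit_kf <- function(X, Y, trial_id = NULL, ridge = 1e-6, add_bias = TRUE) {
  X <- as_matrix2(X, "X"); Y <- as_matrix2(Y, "Y")
  S <- if (add_bias) cbind(Y, 1) else Y
  K <- ncol(S)
  if (nrow(S) < K + 1L) stop_invalid("need at least K+1 paired rows")
  if (qr(S)$rank < K) stop_invalid("rank-deficient state regressors")
  if (is.null(trial_id)) trial_id <- rep(1L, nrow(S))
  within <- which(trial_id[-1L] == trial_id[-length(trial_id)])
  S1 <- S[within, , drop = FALSE]
  S2 <- S[within + 1L, , drop = FALSE]
  At <- solve(crossprod(S1), crossprod(S1, S2))   # S2 ~ S1 %*% At
  A <- t(At)
  resA <- S2 - S1 %*% At
  Q <- crossprod(resA) / max(1L, nrow(resA) - 1L)
  if (add_bias) {                 # the bias component is exactly constant
    A[K, ] <- c(rep(0, K - 1L), 1)
    Q[K, ] <- 0; Q[, K] <- 0
  }
  Ct <- solve(crossprod(S), crossprod(S, X))      # X ~ S %*% Ct
  C <- t(Ct)
  resC <- X - S %*% Ct
  R <- crossprod(resC) / max(1L, nrow(resC) - 1L) + diag(ridge, ncol(X))
  P0 <- stats::cov(S)
  if (add_bias) { P0[K, ] <- 0; P0[, K] <- 0 }
  structure(
    list(A = A, C = C, Q = Q, R = R, x0 = colMeans(S), P0 = P0,
         add_bias = add_bias),
    class = "kf_params"
  )
}

#' @export
print.kf_params <- function(x, ...) {
  cat(sprintf("<kf_params> %d-dim state, %d neurons\n", nrow(x$A), nrow(x$C)))
  invisible(x)
}

#' Kalman-filter decoding
#'
#' Standard predict/update recursion per bin; the state estimate is reset to
#' the fitted initial state at each trial start.
#'
#' @param p A [fit_kf()] result.
#' @param X Neural matrix to decode.
#' @param trial_id Optional per-bin trial labels controlling the resets.
#' @return Predicted kinematics (bins by 2; the bias component is dropped).
#' @export
kf_predict <- function(p, X, trial_id = NULL) {
  X <- as_matrix2(X, "X")
  if (ncol(X) != nrow(p$C)) stop_invalid("X column count does not match C")
  if (is.null(trial_id)) trial_id <- rep(1L, nrow(X))
  K <- nrow(p$A)
  out <- matrix(NA_real_, nrow(X), K)
  s <- p$x0; P <- p$P0
  IK <- diag(K)
  for (t in seq_len(nrow(X))) {
    if (t == 1L || trial_id[t] != trial_id[t - 1L]) {
      # trial start: x0/P0 is the prior of this bin (no propagation)
      s_ <- p$x0
      P_ <- p$P0
    } else {
      s_ <- as.vector(p$A %*% s)
      P_ <- p$A %*% P %*% t(p$A) + p$Q
    }
    Sx <- p$C %*% P_ %*% t(p$C) + p$R
    Kg <- t(solve(Sx, p$C %*% P_))          # P_ C' Sx^{-1}
    s <- s_ + as.vector(Kg %*% (X[t, ] - as.vector(p$C %*% s_)))
    P <- (IK - Kg %*% p$C) %*% P_
    if (any(!is.finite(s)) || any(!is.finite(P))) {
      stop_invalid("numerical failure in Kalman recursion at bin ", t)
    }
    out[t, ] <- s
  }
  out[, 1:2, drop = FALSE]
}

#' Fit the feed-forward network decoder
#'
#' A two-hidden-layer MLP (ReLU, widths 300 and 100 by default) regressing
#' kinematics on neural signals under mean squared error, trained with Adam,
#' with early stopping on validation R-squared (best checkpoint kept; stop
#' after `patience` epochs without a 1% relative improvement). Inputs are
#' z-scored with training-set statistics.
#'
#' @param X,Y Paired neural signals and kinematics.
#' @param train_idx,val_idx Row indices for training and early stopping.
#' @param seed Integer seed; training is deterministic given it.
#' @param widths Hidden widths (default `c(300, 100)`).
#' @param lr,batch_size,max_epochs,patience,rel_tol Optimization settings.
#' @return An object of class `ann_regressor`.
#' @export
fit_ann <- function(X, Y, train_idx = NULL, val_idx = NULL, seed = 1L,
                    widths = c(300L, 100L), lr = 1e-3, batch_size = 256L,
                    max_epochs = 300L, patience = 10L, rel_tol = 0.01) {
  X <- as_matrix2(X, "X"); Y <- as_matrix2(Y, "Y")
  n <- nrow(X)
  if (is.null(train_idx)) {
    val_idx <- with_local_seed(derive_seed(seed, 11L),
                               sample.int(n, max(1L, round(0.2 * n))))
    train_idx <- setdiff(seq_len(n), val_idx)
  }
  if (is.null(val_idx) || length(val_idx) == 0L) {
    stop_invalid("validation rows are required for early stopping")
  }
  ctr <- colMeans(X[train_idx, , drop = FALSE])
  scl <- apply(X[train_idx, , drop = FALSE], 2L, sd)
  scl[scl < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  Xtr <- Xs[train_idx, , drop = FALSE]; Ytr <- Y[train_idx, , drop = FALSE]
  Xva <- Xs[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]
  with_local_seed(seed, {
    net <- mlp_init(c(ncol(X), widths, ncol(Y)))
    flat <- flatten_params(net$layers)
    opt <- adam_init(flat)
    es <- es_init("max", rel_tol = rel_tol, patience = patience)
    best <- flat
    for (epoch in seq_len(max_epochs)) {
      order <- sample.int(nrow(Xtr))
      for (start in seq(1L, length(order), by = batch_size)) {
        idx <- order[start:min(start + batch_size - 1L, length(order))]
        cache <- mlp_fwd(net, Xtr[idx, , drop = FALSE], cache = TRUE)
        dOut <- 2 * (cache$out - Ytr[idx, , drop = FALSE]) / length(cache$out)
        grads <- flatten_params(mlp_bwd(net, cache, dOut)$grads)
        step <- adam_step(flat, grads, opt, lr = lr)
        flat <- step$params; opt <- step$state
        net$layers <- assign_params(net$layers, flat)
      }
      pred_va <- mlp_fwd(net, Xva)
      # constant validation targets leave R2 undefined; fall back to -MSE
      val_r2 <- if (all(apply(Yva, 2L, sd) < 1e-12)) {
        -mean((pred_va - Yva)^2)
      } else {
        r2_score(Yva, pred_va)
      }
      if (!is.finite(val_r2)) stop_invalid("non-finite ANN validation score")
      es <- es_update(es, val_r2, epoch)
      if (es$is_new_best) best <- flat
      if (es$stop) break
    }
    net$layers <- assign_params(net$layers, best)
    structure(list(net = net, center = ctr, scale = scl,
                   widths = as.integer(widths), seed = as.integer(seed),
                   best_val_r2 = es$best),
              class = "ann_regressor")
  })
}

#' @export
print.ann_regressor <- function(x, ...) {
  cat(sprintf("<ann_regressor> hidden widths (%s), best val R2 %.3f\n",
              paste(x$widths, collapse = ", "), x$best_val_r2))
  invisible(x)
}

#' Predict kinematics with a fitted network decoder
#' @param model An [fit_ann()] result.
#' @param X Neural matrix.
#' @return Predicted kinematics.
#' @export
ann_predict <- function(model, X) {
  X <- as_matrix2(X, "X")
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  mlp_fwd(model$net, Xs)
}

#' Decoding R-squared
#'
#' Per kinematic dimension, `1 - SSE/SST` with `SST` about that dimension's
#' mean in `Y`; dimensions are then averaged. Zero-variance dimensions are
#' excluded with a warning.
#'
#' @param Y Observed kinematics.
#' @param Y_hat Predicted kinematics, same shape.
#' @return Scalar R-squared (1 is perfect; 0 matches the mean predictor).
#' @export
r2_score <- function(Y, Y_hat) {
  Y <- as_matrix2(Y, "Y"); Y_hat <- as_matrix2(Y_hat, "Y_hat")
  if (!identical(dim(Y), dim(Y_hat))) stop_invalid("Y and Y_hat shapes differ")
  sst <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  keep <- sst > 0
  if (!any(keep)) stop_invalid("all target dimensions have zero variance")
  if (!all(keep)) warning("excluding zero-variance target dimension(s)")
  sse <- colSums((Y - Y_hat)^2)
  mean(1 - sse[keep] / sst[keep])
}

#' Cross-validated decoding scores
#'
#' For each of the `k` experiments of a fold split: fit the decoder on the
#' training folds (the network decoder early-stops on the validation fold),
#' then score R-squared on the held-out test fold. Reported performance is the
#' mean and standard deviation over the `k` test folds.
#'
#' @param X Neural signal matrix (raw, relevant or irrelevant).
#' @param Y Kinematics.
#' @param split A [make_folds()] result.
#' @param trial_id Per-bin trial labels (from the dataset the split was made
#'   on); used for fold membership and Kalman trial resets.
#' @param decoder `"kf"` or `"ann"`.
#' @param seed Seed for the network decoder.
#' @param signal Optional tag ("raw", "relevant", "irrelevant") carried in the
#'   result.
#' @param ann_widths Hidden widths for the network decoder.
#' @param ann_max_epochs Epoch budget for the network decoder.
#' @return An object of class `decoding_scores`: a list with `scores` (tibble
#'   of per-experiment R-squared), `mean`, `sd`, `decoder`, `signal`.
#' @export
cross_validated_decoding <- function(X, Y, split, trial_id,
                                     decoder = c("kf", "ann"), seed = 1L,
                                     signal = NA_character_,
                                     ann_widths = c(300L, 100L),
                                     ann_max_epochs = 300L) {
  decoder <- match.arg(decoder)
  X <- as_matrix2(X, "X"); Y <- as_matrix2(Y, "Y")
  stopifnot(inherits(split, "fold_split"))
  fake_ds <- list(trial_id = as.integer(trial_id))
  r2 <- numeric(split$k)
  for (e in seq_len(split$k)) {
    rows <- fold_rows(fake_ds, split, e)
    if (decoder == "kf") {
      p <- fit_kf(X[rows$train, , drop = FALSE], Y[rows$train, , drop = FALSE],
                  trial_id = trial_id[rows$train])
      pred <- kf_predict(p, X[rows$test, , drop = FALSE],
                         trial_id = trial_id[rows$test])
    } else {
      fit <- fit_ann(X, Y, train_idx = rows$train, val_idx = rows$validation,
                     seed = derive_seed(seed, e), widths = ann_widths,
                     max_epochs = ann_max_epochs)
      pred <- ann_predict(fit, X[rows$test, , drop = FALSE])
    }
    r2[e] <- r2_score(Y[rows$test, , drop = FALSE], pred)
  }
  structure(
    list(
      scores = tibble::tibble(experiment = seq_len(split$k), r2 = r2),
      mean = mean(r2), sd = sd(r2),
      decoder = decoder, signal = signal
    ),
    class = "decoding_scores"
  )
}

#' @export
print.decoding_scores <- function(x, ...) {
  cat(sprintf("<decoding_scores> %s on %s: R2 = %.3f +/- %.3f (%d folds)\n",
              toupper(x$decoder), x$signal %||% "signals", x$mean, x$sd,
              nrow(x$scores)))
  invisible(x)
}
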