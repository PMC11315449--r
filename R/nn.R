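# Minimal feed-forward network engine: dense layers, ReLU/softplus
# activations, reverse-mode gradients, Adam, gradient clipping, and the
# shared relative-improvement early-stopping rule. Everything operates on
# plain matrices (rows = samples) so BLAS does the heavy lifting.

init_linear <- function(n_in, n_out) {
  # He-style initialization, suitable for the ReLU trunks used throughout
  list(
    W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
    b = numeric(n_out)
  )
}

linear_fwd <- function(p, X) {
  Z <- X %*% p$W
  Z + rep(p$b, each = nrow(Z))
}

linear_bwd <- function(p, X, dZ) {
  list(
    dW = crossprod(X, dZ),
    db = colSums(dZ),
    dX = tcrossprod(dZ, p$W)
  )
}

act_fwd <- function(Z, act) {
  switch(act,
    identity = Z,
    relu = Z * (Z > 0),
    softplus = softplus(Z),
    stop_invalid("unknown activation: ", act)
  )
}

# gradient through the activation, given pre-activation Z
act_bwd <- function(dA, Z, act) {
  switch(act,
    identity = dA,
    relu = dA * (Z > 0),
    softplus = dA * sigmoid(Z),
    stop_invalid("unknown activation: ", act)
  )
}

# An MLP is a list of linear layers plus per-layer activations
# (hidden activation for all but the last, out activation for the last).
mlp_init <- function(sizes, out_act = "identity", hidden_act = "relu") {
  layers <- lapply(seq_len(length(sizes) - 1L), function(i) {
    init_linear(sizes[i], sizes[i + 1L])
  })
  structure(list(layers = layers, hidden_act = hidden_act, out_act = out_act),
            class = "dvaer_mlp")
}

mlp_fwd <- function(net, X, cache = FALSE) {
  L <- length(net$layers)
  acts <- vector("list", L + 1L)
  pres <- vector("list", L)
  acts[[1L]] <- X
  for (i in seq_len(L)) {
    pres[[i]] <- linear_fwd(net$layers[[i]], acts[[i]])
    a <- if (i < L) net$hidden_act else net$out_act
    acts[[i + 1L]] <- act_fwd(pres[[i]], a)
  }
  if (cache) list(out = acts[[L + 1L]], acts = acts, pres = pres) else acts[[L + 1L]]
}

# dOut: gradient of the loss wrt the network output.
# Returns per-layer gradients (named W/b to mirror the parameter layout, so
# the flattened gradient list aligns with the flattened parameters) plus the
# gradient wrt the input.
mlp_bwd <- function(net, cache, dOut) {
  L <- length(net$layers)
  grads <- vector("list", L)
  d <- dOut
  for (i in rev(seq_len(L))) {
    a <- if (i < L) net$hidden_act else net$out_act
    dZ <- act_bwd(d, cache$pres[[i]], a)
    g <- linear_bwd(net$layers[[i]], cache$acts[[i]], dZ)
    grads[[i]] <- list(W = g$dW, b = g$db)
    d <- g$dX
  }
  list(grads = grads, dX = d)
}

# ---- flat parameter plumbing (for Adam and checkpoint fingerprints) ----

# Collect every numeric leaf (W/b matrices and vectors) of a nested model
# list into a flat list, preserving structure for unflattening.
flatten_params <- function(x) {
  out <- list()
  walk <- function(node, path) {
    if (is.numeric(node)) {
      out[[paste(path, collapse = ".")]] <<- node
    } else if (is.list(node)) {
      nm <- names(node) %||% as.character(seq_along(node))
      for (i in seq_along(node)) walk(node[[i]], c(path, nm[i]))
    }
  }
  walk(x, character())
  out
}

assign_params <- function(x, flat) {
  walk <- function(node, path) {
    if (is.numeric(node)) {
      return(flat[[paste(path, collapse = ".")]])
    }
    if (is.list(node)) {
      nm <- names(node) %||% as.character(seq_along(node))
      for (i in seq_along(node)) node[[i]] <- walk(node[[i]], c(path, nm[i]))
    }
    node
  }
  walk(x, character())
}

adam_init <- function(flat) {
  list(
    m = lapply(flat, function(p) p * 0),
    v = lapply(flat, function(p) p * 0),
    t = 0L
  )
}

# One Adam update on a flat parameter list; gradients are clipped to a global
# L2 norm of `clip` before the moment updates.
adam_step <- function(flat, grads, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  if (!identical(sort(names(flat)), sort(names(grads)))) {
    stop_invalid("parameter/gradient name mismatch")
  }
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(clip) && gnorm > clip) {
    grads <- lapply(grads, function(g) g * (clip / gnorm))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(flat)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    flat[[k]] <- flat[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = flat, state = state)
}

# ---- early stopping ----
# Shared rule: track the best validation criterion; if no epoch improves the
# best by at least `rel_tol` (relative, 1% by default) within `patience`
# epochs, stop. `mode` is "min" for losses, "max" for R-squared.
es_init <- function(mode = c("min", "max"), rel_tol = 0.01, patience = 10L) {
  mode <- match.arg(mode)
  list(mode = mode, rel_tol = rel_tol, patience = as.integer(patience),
       best = if (mode == "min") Inf else -Inf, best_epoch = 0L,
       since_signif = 0L, stop = FALSE)
}

es_update <- function(es, value, epoch) {
  better <- if (es$mode == "min") value < es$best else value > es$best
  signif_improve <- if (!is.finite(es$best)) {
    better
  } else if (es$mode == "min") {
    value < es$best - es$rel_tol * abs(es$best)
  } else {
    value > es$best + es$rel_tol * abs(es$best)
  }
  es$is_new_best <- better
  if (better) {
    es$best <- value
    es$best_epoch <- epoch
  }
  if (signif_improve) {
    es$since_signif <- 0L
  } else {
    es$since_signif <- es$since_signif + 1L
    if (es$since_signif >= es$patience) es$stop <- TRUE
  }
  es
}
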