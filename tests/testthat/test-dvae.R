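test_that("poisson reconstruction loss matches the scalar formula", {
  expect_equal(poisson_nll(matrix(1, 2, 2), matrix(1, 2, 2)), 1)
  r <- matrix(c(0.5, 2, 1.5, 3), 2)
  expect_equal(poisson_nll(r, matrix(0, 2, 2)), mean(r))
  # fixed 2x2 plug-in oracle
  x <- matrix(c(1, 0, 2, 3), 2)
  expect_equal(poisson_nll(r, x), mean(r - x * log(r)), tolerance = 1e-12)
  # minimized at rate = target
  expect_lt(poisson_nll(x + 1e-9, x, check_targets = TRUE),
            poisson_nll(x * 1.3 + 0.1, x))
  expect_error(poisson_nll(r, -x), "negative")
  expect_silent(poisson_nll(r, x - 2, check_targets = FALSE))
})

test_that("diagonal-Gaussian KL matches closed form and quadrature", {
  m <- matrix(rnorm(6), 2)
  v <- matrix(runif(6, 0.5, 2), 2)
  expect_equal(gaussian_kl(m, v, m, v), 0)
  expect_equal(gaussian_kl(1, 1, 0, 1), 0.5)
  expect_error(gaussian_kl(m, -v, m, v), "positive")
  # 3-D case against numerical integration (KL factorizes over dimensions)
  set.seed(4)
  mp <- rnorm(3); vp <- runif(3, 0.5, 2)
  mq <- rnorm(3); vq <- runif(3, 0.5, 2)
  kl1 <- function(mp, vp, mq, vq) {
    integrand <- function(z) {
      p <- dnorm(z, mp, sqrt(vp))
      p * (dnorm(z, mp, sqrt(vp), log = TRUE) - dnorm(z, mq, sqrt(vq), log = TRUE))
    }
    integrate(integrand, -30, 30, rel.tol = 1e-10)$value
  }
  num <- sum(mapply(kl1, mp, vp, mq, vq))
  expect_equal(gaussian_kl(rbind(mp), rbind(vp), rbind(mq), rbind(vq)), num,
               tolerance = 1e-3)
})

test_that("reparameterization is mu + sigma * eps elementwise", {
  post <- list(mu = rbind(c(1, 2)), log_var = rbind(2 * log(c(1, 0.5))))
  expect_equal(reparameterize(post, rbind(c(0, 0))), rbind(c(1, 2)))
  expect_equal(reparameterize(post, rbind(c(2, -2))), rbind(c(3, 1)))
  zero_var <- list(mu = rbind(c(1, 2)), log_var = rbind(c(-Inf, -Inf)))
  expect_equal(reparameterize(zero_var, rbind(c(5, -5))), rbind(c(1, 2)))
  expect_error(reparameterize(post, rbind(c(0, 0, 0))), "shape")
})

test_that("the inference network computes the documented affine-rectifier stack", {
  cfg <- dvae_config(latent_dim = 2, encoder_widths = 3L, prior_width = 4L,
                     seed = 1)
  model <- dvae_init(2, cfg)
  # fixed tiny weights, hand-computed forward pass on a 2-neuron toy
  W1 <- matrix(c(0.5, -1, 1, 0.25, -0.5, 2), 2, 3)
  b1 <- c(0.1, -0.2, 0)
  Wm <- matrix(c(1, 0, -1, 0.5, 2, 0), 3, 2)
  model$f_trunk$layers[[1]] <- list(W = W1, b = b1)
  model$f_mu <- list(W = Wm, b = c(0.3, -0.3))
  model$f_lv <- list(W = matrix(0, 3, 2), b = c(-1, -2))
  x <- rbind(c(1, 2), c(0.5, 0))
  h_hand <- pmax(x %*% W1 + rep(b1, each = 2), 0)
  mu_hand <- h_hand %*% Wm + rep(c(0.3, -0.3), each = 2)
  post <- infer_posterior(model, x)
  expect_equal(post$mu, mu_hand, tolerance = 1e-12)
  expect_equal(post$log_var, matrix(rep(c(-1, -2), each = 2), 2),
               tolerance = 1e-12)
  expect_true(all(exp(post$log_var) > 0))
  expect_error(infer_posterior(model, cbind(x, 1)), "columns")
  # identity trunk + identity mean head reproduce non-negative inputs
  idm <- dvae_init(2, dvae_config(latent_dim = 2, encoder_widths = 2L,
                                  prior_width = 3L, seed = 2))
  idm$f_trunk$layers[[1]] <- list(W = diag(2), b = c(0, 0))
  idm$f_mu <- list(W = diag(2), b = c(0, 0))
  xpos <- matrix(c(0.3, 1.2, 0, 4), 2)
  expect_equal(infer_posterior(idm, xpos)$mu, xpos)
})

test_that("decoding losses share f and h across the two paths and average", {
  cfg <- dvae_config(latent_dim = 3, encoder_widths = c(6L, 4L),
                     prior_width = 5L, seed = 3)
  model <- dvae_init(4, cfg)
  x <- matrix(abs(rnorm(20)), 5, 4)
  y <- matrix(0, 5, 2)
  # readout forced to output y = 0 exactly
  model$h <- list(W = matrix(0, 3, 2), b = c(0, 0))
  losses <- decoding_losses(model, x, y)
  expect_equal(losses$ldec1, 0)
  expect_equal(losses$ldec2, 0)
  # arithmetic mean of the two components
  model2 <- dvae_init(4, cfg)
  l2 <- decoding_losses(model2, x, matrix(rnorm(10), 5),
                        eps = matrix(0, 5, 3))
  expect_equal(l2$ldec, (l2$ldec1 + l2$ldec2) / 2)
})

test_that("total loss weighs components as L = Lrec + beta*LKL + alpha*Ldec", {
  cfg0 <- dvae_config(alpha = 0, beta = 0)
  expect_equal(total_loss(1.7, 99, 42, cfg0), 1.7)
  cfg <- dvae_config(alpha = 0.3, beta = 0.001)
  expect_equal(total_loss(1, 2, 3, cfg), 1.902)
  # default KL weight
  expect_equal(dvae_config()$beta, 0.001)
  # default early stopping rule: 1% improvement within 10 epochs
  expect_equal(dvae_config()$rel_tol, 0.01)
  expect_equal(dvae_config()$patience, 10L)
})

test_that("analytic gradients match finite differences on a toy model", {
  set.seed(7)
  cfg <- dvae_config(latent_dim = 3, alpha = 0.6, beta = 0.02,
                     encoder_widths = c(5L, 4L), prior_width = 6L, seed = 7)
  model <- dvae_init(4, cfg)
  X <- matrix(abs(rnorm(28)) + 0.3, 7)
  Y <- matrix(rnorm(14), 7)
  eps <- matrix(rnorm(21), 7)
  bg <- dvaer:::dvae_batch_grad(model, X, Y, eps)
  flat <- dvaer:::flatten_params(dvaer:::dvae_param_list(model))
  g <- dvaer:::flatten_params(bg$grads)
  h <- 1e-6
  for (nm in names(flat)) {
    for (i in sample(seq_along(flat[[nm]]), min(3, length(flat[[nm]])))) {
      f2 <- flat
      f2[[nm]][i] <- f2[[nm]][i] + h
      m2 <- dvaer:::dvae_set_params(
        model, dvaer:::assign_params(dvaer:::dvae_param_list(model), f2))
      num <- (dvaer:::dvae_batch_grad(m2, X, Y, eps)$losses[["total"]] -
                bg$losses[["total"]]) / h
      expect_equal(g[[nm]][i], num, tolerance = 5e-3)
    }
  }
})

test_that("training is deterministic, improves decoding, and reduces KL", {
  set.seed(11)
  # linear toy: kinematics exactly affine in the counts
  n <- 240L
  X <- matrix(runif(n * 4, 0, 3), n)
  W <- matrix(c(0.5, -0.3, 0.2, 0.1, -0.4, 0.6, 0, 0.2), 4)
  ds <- binned_dataset(X, X %*% W, trial_id = rep(1:24, each = 10))
  split <- make_folds(ds, 4, seed = 1)
  cfg <- tiny_config(seed = 5)
  fit1 <- train_dvae(ds, split, 1, cfg)
  fit2 <- train_dvae(ds, split, 1, cfg)
  expect_identical(fit1$trace, fit2$trace)
  tr <- fit1$trace
  # a realizable decoding objective must beat the initial readout
  expect_lt(tail(tr$val_ldec1, 1), tr$val_ldec1[1])
  # alignment pressure acted: KL finite and below its initial value
  expect_true(is.finite(tail(tr$val_lkl, 1)))
  expect_lt(tail(tr$val_lkl, 1), tr$val_lkl[1])
  # the saved checkpoint is the best validation total loss seen at save points
  expect_equal(attr(tr, "best_epoch"), which.min(tr$val_total))
  # vacuous budget returns the initialized model and an empty trace
  fit0 <- train_dvae(ds, split, 1, tiny_config(max_epochs = 0L, seed = 5))
  expect_false(isTRUE(attr(fit0$model, "trained")))
  expect_equal(nrow(fit0$trace), 0L)
})

test_that("distillation is exactly additive with non-negative relevant part", {
  ds <- tiny_dataset(n_trials = 8, bins = 8, n_neurons = 5, seed = 3)
  split <- make_folds(ds, 4, seed = 2)
  fit <- train_dvae(ds, split, 1, tiny_config(max_epochs = 4L, seed = 3))
  dec <- distill(fit$model, ds)
  expect_identical(dec$raw - dec$relevant - dec$irrelevant,
                   matrix(0, nrow(ds$counts), 5))
  expect_true(all(dec$relevant >= 0))
  expect_error(distill(fit$model, ds$counts[, 1:3]), "columns")
  # prior-path generation produces positive rates of the right shape
  gen <- generate_from_kinematics(fit$model, ds$kinematics)
  expect_equal(dim(gen), dim(ds$counts))
  expect_true(all(gen > 0))
})

test_that("checkpoints round-trip and verify the data fingerprint", {
  ds <- tiny_dataset(seed = 4)
  split <- make_folds(ds, 3, seed = 1)
  fit <- train_dvae(ds, split, 1, tiny_config(max_epochs = 2L, seed = 4))
  path <- tempfile(fileext = ".rds")
  save_dvae(fit$model, path, ds = ds)
  loaded <- load_dvae(path, ds = ds)
  expect_identical(distill(loaded, ds)$relevant, distill(fit$model, ds)$relevant)
  other <- tiny_dataset(seed = 99)
  expect_error(load_dvae(path, ds = other), "fingerprint")
})
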