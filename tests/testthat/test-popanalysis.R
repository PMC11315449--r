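test_that("cosine tuning recovers planted preferred directions", {
  set.seed(1)
  n <- 1e4
  theta <- runif(n, 0, 2 * pi)
  speed <- runif(n, 0, 3)
  V <- cbind(speed * cos(theta), speed * sin(theta))
  counts <- cbind(
    4 + cos(theta - pi / 4) * speed,   # planted PD at pi/4, always positive
    rnorm(n) + 2                       # untuned white noise around 2
  )
  fit <- cosine_tuning_fit(counts, V)
  expect_lt(abs(fit$pd_rad[1] - pi / 4), 1e-6)
  expect_gt(fit$r_squared[1], 0.99)
  expect_lt(abs(fit$r_squared[2]), 0.02)
  # positive scaling leaves the preferred direction unchanged
  fit2 <- cosine_tuning_fit(cbind(3.7 * counts[, 1]), V)
  expect_equal(fit2$pd_rad, fit$pd_rad[1], tolerance = 1e-10)
  expect_error(cosine_tuning_fit(counts, matrix(1, n, 2)), "singular|collinear")
})

test_that("preferred-direction deviations use the minimal circular difference", {
  mk <- function(pd) tibble::tibble(neuron = seq_along(pd), b0 = 0,
                                    bx = cos(pd), by = sin(pd),
                                    pd_rad = pd, r_squared = 1)
  expect_equal(pd_angle_difference(mk(c(0.3, 1)), mk(c(0.3, 1))), c(0, 0))
  expect_equal(pd_angle_difference(mk(pi / 2), mk(-pi / 2)), 180)
  expect_equal(pd_angle_difference(mk(10 * pi / 180), mk(350 * pi / 180)), 20,
               tolerance = 1e-10)
})

test_that("Fano factors behave like variance over mean of trial-aligned counts", {
  # identical trials: zero variability
  one_trial <- matrix(rpois(20, 3), 10, 2)
  ds <- binned_dataset(do.call(rbind, rep(list(one_trial), 5)),
                       matrix(rnorm(100), 50),
                       trial_id = rep(1:5, each = 10))
  ff <- fano_factor(ds)
  expect_true(all(ff$fano == 0))
  # i.i.d. Poisson(4): FF within 0.1 of 1 at 200 trials
  set.seed(2)
  n_tr <- 200; bins <- 10
  pois <- matrix(rpois(n_tr * bins * 2, 4), n_tr * bins, 2)
  dsp <- binned_dataset(pois, matrix(rnorm(n_tr * bins * 2), n_tr * bins),
                        trial_id = rep(seq_len(n_tr), each = bins))
  ffp <- fano_factor(dsp)
  expect_true(all(abs(ffp$fano - 1) < 0.1))
  # doubling all counts doubles the Fano factor
  ds2 <- dsp; ds2$counts <- 2 * dsp$counts
  expect_equal(fano_factor(ds2)$fano, 2 * ffp$fano, tolerance = 1e-12)
  # conditions with fewer than two trials are excluded with a warning
  dsc <- binned_dataset(pois[1:30, ], matrix(0.5, 30, 2),
                        trial_id = rep(1:3, each = 10),
                        condition_id = c(1L, 1L, 2L))
  expect_warning(ffc <- fano_factor(dsc), "excluded")
  expect_true(all(ffc$condition == 1))
})

test_that("PCA reports and alignment index agree with brute-force algebra", {
  set.seed(3)
  iso <- matrix(rnorm(4000), 2000)
  rep_iso <- pca_variance_curve(iso)
  expect_equal(rep_iso$eigenvalues / sum(rep_iso$eigenvalues),
               c(0.5, 0.5), tolerance = 0.1)
  expect_equal(rep_iso$dim_at, 2L)
  rank1 <- outer(rnorm(100), c(1, 2, -1))
  expect_equal(pca_variance_curve(rank1)$dim_at, 1L)
  # eigenvalues match a dense covariance eigendecomposition
  X <- matrix(rnorm(500), 100, 5)
  rep5 <- pca_variance_curve(X)
  expect_equal(rep5$eigenvalues, eigen(cov(X), symmetric = TRUE)$values,
               tolerance = 1e-10)
  # alignment: full basis captures exactly 100%
  expect_equal(alignment_index(X, diag(5)), 100, tolerance = 1e-10)
  # brute-force projected-variance oracle on 6-neuron data
  X6 <- matrix(rnorm(1200), 200, 6)
  D <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  brute <- 100 * sum(apply(X6 %*% D, 2, var)) / sum(apply(X6, 2, var))
  expect_equal(alignment_index(X6, D), brute, tolerance = 1e-10)
  # isotropic data: d axes capture ~ d/N of the variance
  iso6 <- matrix(rnorm(6 * 4000), ncol = 6)
  expect_equal(alignment_index(iso6, D), 50, tolerance = 5)
  expect_error(alignment_index(X6, D * 2), "orthonormal")
})

test_that("variance composition satisfies the exact conservation identity", {
  set.seed(4)
  rel <- matrix(runif(300, 0.5, 2), 100, 3)
  # irrelevant identically zero
  dec0 <- signal_decomposition(rel, rel)
  vc0 <- variance_composition(dec0)
  expect_equal(vc0$per_unit$var_irrelevant, rep(0, 3))
  expect_equal(vc0$per_unit$covariance2, rep(0, 3))
  expect_equal(vc0$per_unit$var_raw, vc0$per_unit$var_relevant)
  # y = -x: raw is constant, 2Cov = -2 Var(x)
  decm <- signal_decomposition(rel * 0, rel)
  vcm <- variance_composition(decm)
  expect_equal(vcm$per_unit$var_raw, rep(0, 3))
  expect_equal(vcm$per_unit$covariance2, -2 * vcm$per_unit$var_relevant,
               tolerance = 1e-12)
  # conservation on random decompositions, per neuron and per PC
  raw <- rel + matrix(rnorm(300), 100)
  dec <- signal_decomposition(raw, rel)
  vc <- variance_composition(dec)
  resid <- with(vc$per_unit, var_relevant + var_irrelevant + covariance2 - var_raw)
  expect_true(all(abs(resid) < 1e-10))
  basis <- pca_variance_curve(raw)$axes
  vcp <- variance_composition(dec, basis = basis)
  residp <- with(vcp$per_unit, var_relevant + var_irrelevant + covariance2 - var_raw)
  expect_true(all(abs(residp) < 1e-10))
  expect_true(vcp$marker_index %in% 0:3)
  expect_equal(glance(vc)$var_raw, sum(vc$per_unit$var_raw))
})

test_that("neuron reordering is a permutation and recovers planted blocks", {
  set.seed(5)
  for (n in c(7, 20, 33)) {
    C <- cov2cor(crossprod(matrix(rnorm(n * (n + 5)), n + 5, n)))
    ord <- reorder_neurons(C)
    expect_perm(ord$order, n)
  }
  # two 10-neuron blocks: within 0.9, across 0
  blk <- matrix(0, 20, 20)
  blk[1:10, 1:10] <- 0.9
  blk[11:20, 11:20] <- 0.9
  diag(blk) <- 1
  ordb <- reorder_neurons(blk)
  expect_length(ordb$groups, 2L)
  expect_true(setequal(ordb$groups[[1]], 1:10) || setequal(ordb$groups[[1]], 11:20))
  expect_true(setequal(union(ordb$groups[[1]], ordb$groups[[2]]), 1:20))
  # 10-neuron hand trace: seed is the row of the max off-diagonal value,
  # remaining members follow in descending correlation to the seed
  C10 <- diag(10)
  C10[2, 7] <- C10[7, 2] <- 0.95
  sims <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2)
  others <- setdiff(1:10, c(2, 7))
  for (i in seq_along(others)) {
    C10[2, others[i]] <- C10[others[i], 2] <- sims[i]
  }
  ord10 <- reorder_neurons(C10)
  expect_equal(ord10$order[1:2], c(2L, 7L))
  expect_equal(ord10$order[3:10], others)
  expect_error(reorder_neurons(matrix(0, 2, 3)), "square")
})

test_that("dropout curves start at the full population and shrink to one neuron", {
  ds <- tiny_dataset(n_trials = 10, bins = 12, n_neurons = 5, seed = 7)
  ds$kinematics <- ds$counts[, 1:2] + 0.3 * matrix(rnorm(240), 120)
  split <- make_folds(ds, 5, seed = 1)
  dec <- signal_decomposition(ds$counts, ds$counts)  # relevant == raw
  tun <- cosine_tuning_fit(ds$counts, ds$kinematics)
  curve <- dropout_curve(dec, tun, ds$kinematics, split, ds$trial_id,
                         decoder = "kf")
  full <- cross_validated_decoding(ds$counts, ds$kinematics, split,
                                   ds$trial_id, decoder = "kf")
  expect_equal(curve$mean_r2[curve$n_dropped == 0 & curve$signal == "raw"],
               full$mean)
  # raw and relevant curves coincide for the trivial decomposition
  expect_equal(curve$mean_r2[curve$signal == "raw"],
               curve$mean_r2[curve$signal == "relevant"])
  # boundary: all but one dropped equals single-neuron decoding
  last_kept <- order(tun$r_squared, decreasing = TRUE)[5]
  single <- cross_validated_decoding(ds$counts[, last_kept, drop = FALSE],
                                     ds$kinematics, split, ds$trial_id,
                                     decoder = "kf")
  expect_equal(curve$mean_r2[curve$n_dropped == 4 & curve$signal == "raw"],
               single$mean)
})

test_that("cumulative-PC decoding is lossless at full rank and ordered correctly", {
  set.seed(8)
  ds <- tiny_dataset(n_trials = 10, bins = 12, n_neurons = 4, seed = 8)
  ds$kinematics <- ds$counts[, 1:2] + 0.3 * matrix(rnorm(240), 120)
  split <- make_folds(ds, 5, seed = 1)
  curve <- cumulative_pc_decoding(ds$counts, ds$kinematics, split, ds$trial_id,
                                  order = "descending", decoder = "kf")
  expect_equal(nrow(curve), 4L)
  full <- cross_validated_decoding(ds$counts, ds$kinematics, split,
                                   ds$trial_id, decoder = "kf")
  expect_lt(abs(curve$mean_r2[curve$m == 4] - full$mean), 1e-6)
  # rank-1-dominated fixture: the smallest PC carries no target signal
  n <- 200
  sig <- rnorm(n)
  Xr <- cbind(5 * sig, 5 * sig + 0.01 * rnorm(n), 0.01 * rnorm(n))
  Yr <- cbind(sig, 0.6 * sig + 0.8 * rnorm(n))
  tid <- rep(1:20, each = 10)
  spr <- make_folds(list(trial_id = tid), 5, seed = 1)
  asc <- cumulative_pc_decoding(Xr, Yr, spr, tid, order = "ascending",
                                decoder = "kf", m_values = 1L)
  expect_lt(asc$mean_r2, 0.1)
})

test_that("speed-region splitting balances error mass at the first grid crossing", {
  set.seed(9)
  n <- 2000
  theta <- runif(n, 0, 2 * pi)
  speed <- runif(n, 0, 40)
  Y <- cbind(speed * cos(theta), speed * sin(theta))
  # uniform per-sample error, symmetric speeds: threshold near the median speed
  pred <- Y + cbind(rep(1, n), rep(-1, n)) / sqrt(2)
  sp <- split_speed_regions(Y, pred)
  expect_equal(sp$Ep_low + sp$Ep_high, sp$Ep)
  expect_lt(abs(sp$threshold - stats::median(speed)), 2)
  # first-crossing property on the enumeration grid
  expect_gte(sp$Ep_low, 0.5 * sp$Ep)
  err <- sp$per_sample_error
  sp_speed <- sqrt(rowSums(Y^2))
  prev <- sp$threshold - 0.1
  expect_lt(sum(err[sp_speed < prev]), 0.5 * sp$Ep)
  # default grid bounds
  expect_equal(eval(formals(split_speed_regions)$speed_grid)[1], 1)
  expect_error(split_speed_regions(Y * 10, pred * 10), "extend")
})

test_that("improvement ratios follow the stated sign conventions", {
  set.seed(10)
  n <- 500
  Y <- cbind(runif(n, 0, 30), runif(n, -30, 30))
  pred <- Y + matrix(rnorm(2 * n), n)
  sp <- split_speed_regions(Y, pred)
  # no change
  rep0 <- improvement_ratios(sp, sp$per_sample_error)
  expect_equal(rep0$air_low, 0)
  expect_equal(rep0$air_high, 0)
  expect_true(all(rep0$rir$rir == 0))
  # error halved in the low region -> AIR_low = 0.5
  e2 <- sp$per_sample_error
  e2[sp$low_mask] <- e2[sp$low_mask] / 2
  expect_equal(improvement_ratios(sp, e2)$air_low, 0.5)
  # error doubled -> AIR = -1
  expect_equal(improvement_ratios(sp, 2 * sp$per_sample_error)$air_low, -1)
  # zero-baseline samples excluded and counted
  sp0 <- sp
  sp0$per_sample_error[1:3] <- 0
  rep_z <- improvement_ratios(sp0, sp0$per_sample_error)
  expect_equal(rep_z$n_zero_excluded, 3L)
  expect_false(any(rep_z$rir$sample %in% 1:3))
})
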