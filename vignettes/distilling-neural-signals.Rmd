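---
title: "Separating behaviorally relevant from irrelevant neural population activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating behaviorally relevant from irrelevant neural population activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvaer)
```

## The problem and the model

A binned spike-count matrix `x` (time bins by neurons, 100 ms bins by
default) time-aligned to 2-D velocity `y` mixes behaviorally relevant
activity with noise and activity tied to unmeasured variables. `dvaer`
decomposes `x = x_r + x_i` where the relevant part `x_r` is generated by a
variational autoencoder and the irrelevant part is *defined* as the residual,
so additivity is exact by construction and `x_r >= 0` (it is a rate).

The generative model is `p(x | y) = ∫ p_m(z | y) p_g(x | z) dz`: a learned
behavior-conditioned prior `m(y)` over the latent state and a Poisson-type
observation model through the generator `g`. The inference network `f` sees
only `x` — at analysis time no kinematics are needed to distill a recording.
The training loss combines

* a Poisson reconstruction term (continuous form `rate − x·log rate`,
  the `log x!` constant dropped so fractional smoothed counts are valid
  targets),
* a KL alignment term between the learned prior and the posterior, taken in
  the direction `KL(prior ‖ posterior)` (a configuration switch selects the
  conventional reverse direction), and
* two decoding mean-squared errors through one shared affine readout `h`:
  from the posterior mean of the raw signals and from the posterior mean of
  the *generated* signals re-encoded through the same `f`. The second path is
  what prevents the generator from smuggling irrelevant activity into `x_r`:
  anything that does not help decode behavior costs decoding accuracy.

The assumptions worth stating plainly: time bins are treated as exchangeable
samples (the networks have no recurrence, so temporal dynamics enter only
through the kinematics themselves); behaviorally irrelevant activity acts
like noise for decoding; and "relevant" is operationalized against the
*measured* behavioral variables — activity encoding unmeasured variables
lands in the irrelevant partition by definition.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.9 | weight of the decoding loss; the reconstruction/decoding trade-off that defines the separation. Selected by `sweep_alpha()` + `select_alpha()` (criterion `0.75·Dre + 0.25·(1 − Dir)`, ties to the smaller value). 0.9 is the selected value for the synthetic benchmark; real recordings typically select 0.1–0.9. |
| `beta` | 0.001 | KL weight (dimensionless). Deliberately small: the prior is itself learned, and a strong pull degrades both reconstruction and decoding while a weak one still aligns the posterior. |
| `latent_dim` | 50 | latent dimensionality `d`. |
| `encoder_widths` | 300, 100 | hidden ReLU widths of `f`; `g` is symmetric with a softplus output. Prior net `m` has one hidden layer of 300. |
| `lr`, `batch_size` | 1e-3, 256 | Adam step size and minibatch size (bins); gradients clipped at global norm 5. |
| `patience`, `rel_tol` | 10, 0.01 | early stopping: keep the best-validation-loss checkpoint; stop when no epoch improves the best by 1% (relative) within 10 epochs. The same rule (on validation R² instead of loss) governs the network decoder and the fitted encoder. |
| `min_rate_hz` | 0.5 | neuron exclusion threshold on mean rate. |
| `window` | 3 | moving-average smoothing window, bins. |

Velocity units: the losses mix a Poisson NLL of order 1 per bin with
velocity MSEs in task units, which for cm/s-scale center-out data are of
order 100. `train_dvae()` therefore z-scores the velocities with
training-fold statistics before computing the decoding losses (the scaling is
stored in the model; every user-facing prediction is returned in original
units). Without this, the decoding term dominates the total loss and the 1%
early-stopping rule fires on the decoding floor before the reconstruction
has converged. The velocity scale is thereby absorbed, so `alpha` has the
same meaning across datasets with different units.

## The synthetic benchmark

`simulate_synthetic_dataset()` builds the reference study conditions used
throughout the tests:

* **Kinematics** — an 8-direction center-out task, 200 trials of 18 bins,
  bell-shaped speed profiles with across-trial amplitude variation (peak
  speed 20 ± 3 in arbitrary velocity units) and small direction jitter
  (0.08 rad). These values are what we consider a realistic center-out
  session at 100 ms resolution; they are fixed once here and are not tuned.
* **Encoder** — each neuron maps velocity to a rate through
  `softplus(b0 + (1−m)(bx·vx + by·vy) + m·c·φ(v))`. Nine strongly tuned
  neurons use mixing `m = 0` (exactly affine before the positivity map,
  baseline 1–2 counts/bin, modulation depth 0.04–0.10 per unit speed); three
  weakly tuned neurons use `m = 1` with `φ` combining a speed-quadratic term
  and direction harmonics of order 2 **and** 3. Harmonics of order ≥ 2 are
  orthogonal to the affine velocity model under a symmetric direction design,
  which keeps the weak neurons' linear tuning R² below 0.01; including both
  orders 2 and 3 makes direction *jointly identifiable* from the population
  (order 2 alone leaves direction ambiguous modulo π, which would make the
  weak neurons nonlinearly undecodable too — an ambiguity we want the
  benchmark to avoid). Parameters are resampled within a bounded budget until
  every neuron verifiably lands in its tuning class, checked with the same
  `cosine_tuning_fit()` used for analysis.
* **Noise** — white Gaussian noise rescaled *deterministically after the
  draw* so the realized aggregate power ratio equals the requested 7 dB
  exactly (power = mean square over all entries, the standard additive
  white-Gaussian-noise convention; a `per_neuron` flag enforces the ratio
  column-wise instead). The noisy sum is stored unfloored — raw synthetic
  signals may be negative — because flooring would break the exact additivity
  of the ground-truth decomposition. `poisson_nll()` consequently accepts
  negative targets only when its validity check is disabled, which is what
  the training loop does; the continuous loss remains well defined.
* An optional `poisson_counts` mode draws integer counts
  `Poisson(relevant)` instead, for realism studies; it is not the default
  because the additive-Gaussian construction is the one with a controllable
  SNR.

What the generator does **not** emulate: spike-sorting artifacts, electrode
drift, non-stationarity, correlated (non-white) noise, and temporal
autocorrelation of the irrelevant component. Passing tests on this benchmark
therefore demonstrate correctness of the machinery and recoverability under
idealized noise, not performance on any particular real recording.

`fit_encoder()` (kinematics → rates MLP, 500/500 ReLU units, softplus
output, Poisson NLL) is provided for users who want to derive a ground-truth
encoder from their own recordings instead of the parametric one.

## Numerical choices and degenerate inputs

* Moving-average smoothing uses a centered window with shrinking edge
  windows, applied within trials only; a centered filter keeps the counts
  aligned with the kinematics (a causal filter would introduce phase lag).
  Low-rate exclusion is applied to unsmoothed counts; in the interior the
  filter is mean-preserving, so rates are essentially unaffected by the
  order.
* Folds are whole-trial assignments (seeded permutation, contiguous
  chunking): bin-level splits would leak temporally adjacent bins between
  train and test. Recordings without trial markers are segmented into
  10-bin pseudo-trials first.
* Posterior variances are parameterized as log-variance heads. Rates are
  floored at 1e-8 inside the Poisson loss (gradient zero where the floor
  binds). Test-time distillation uses the posterior mean, never a sample, so
  downstream analyses are reproducible.
* The Kalman state is velocity augmented with a constant-1 bias component to
  absorb baseline firing; `R` is ridge-regularized (+1e-6 on the diagonal).
  At a trial start the fitted initial state/covariance act as the prior of
  the first bin (no propagation step). Rank-deficient regressors raise an
  explicit error rather than producing silent pseudo-inverse fits.
* `r2_score()` averages per-dimension `1 − SSE/SST` over the two velocity
  components (SST about the test-set mean); zero-variance dimensions are
  excluded with a warning. Negative values are never clipped — catastrophic
  settings should rank as catastrophic, in particular inside the α-selection
  criterion.
* The speed-region split takes the *first* grid point at which the
  cumulative squared error of slower samples reaches half the total, which
  under a monotone cumulative sum is the grid value closest to the half-mass
  point from above; `Ep_low + Ep_high = Ep` holds exactly because the regions
  partition the samples. The 1–50 step 0.1 enumeration grid presumes
  task-typical speed units and is configurable.
* `reorder_neurons()` breaks ties in the seed-selection step toward the
  smaller neuron index, making the grouping deterministic.

## Known limitations

* No temporal model: the latent state is inferred bin by bin. Sequence
  structure in the irrelevant component (e.g. slow drift) is not separable
  from signal by this architecture.
* The Poisson reconstruction term treats Gaussian-noised synthetic rates as
  counts; with heavy noise the negative bins push generated rates downward,
  a small systematic bias of the synthetic benchmark rather than of real
  count data.
* A least-squares Kalman filter applied to *noise-free, purely nonlinearly
  tuned* signals (the ground-truth weak neurons) can score strongly negative
  R² rather than ≈ 0: the fitted velocity dynamics are nearly unit-root, and
  the smooth nonlinear modulation enters the innovation where tiny
  finite-sample linear couplings integrate into large coherent excursions
  within a trial. The test suite computes this behavior directly; it is a
  property of the linear filter on this class of signals, not of the
  distillation, and it makes before/after comparisons of *linear*
  decodability on such signals delicate — the nonlinear decoder comparison is
  the informative one there.
* Problem sizes in the test suite (200 trials × 18 bins × 12 neurons for the
  end-to-end checks; a 50-epoch budget for the reduced-budget training run;
  smaller nets for unit tests) are the package's chosen reference scales;
  results at those scales are what the tests assert.

## A minimal session

```{r example, eval = FALSE}
sds <- simulate_synthetic_dataset(seed = 1)
ds <- sds$dataset
split <- make_folds(ds, 5, seed = 1)
fit <- train_dvae(ds, split, 1, dvae_config(max_epochs = 50, seed = 1))
dec <- distill(fit$model, ds)

mean(per_neuron_similarity(dec$relevant, sds$ground_truth_relevant))
cross_validated_decoding(dec$relevant, ds$kinematics, split, ds$trial_id,
                         decoder = "ann")

# single-neuron and population structure after separation
tun_raw <- cosine_tuning_fit(dec$raw, ds$kinematics)
tun_rel <- cosine_tuning_fit(dec$relevant, ds$kinematics)
pd_angle_difference(tun_raw, tun_rel)
variance_composition(dec, basis = pca_variance_curve(dec$raw)$axes)
```
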