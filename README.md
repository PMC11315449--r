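# dvaer — distilling behaviorally relevant signals from neural population activity

Binned spike counts recorded from motor cortex mix two kinds of activity: a
component that encodes the measured behavior (here, 2-D movement velocity)
and everything else — noise plus activity tied to unmeasured variables. The
mixture distorts single-neuron tuning estimates, inflates trial-to-trial
variability, and hides how much behavioral information weakly tuned neurons
actually carry. `dvaer` separates the two components at single-neuron,
single-trial resolution and provides the decoders and population analyses
needed to validate and interrogate the separation. It is aimed at
neurophysiologists and BCI researchers working with trial-structured
population recordings time-aligned to continuous kinematics.

## The model

The distillation variational autoencoder (d-VAE) treats the raw signal
`x ∈ R^n` per time bin as generated from a latent state `z ∈ R^d` that is
tied to the kinematics `y ∈ R^k`:

* inference network `f : x → (μ, σ²)`, posterior `q_f(z | x) = N(μ, σ²)`;
* generator `g : z → x_r` with softplus output, so the generated
  behaviorally relevant signal `x_r` is a positive rate;
* behavior-conditioned learned prior `m : y → N(μ_p, σ_p²)`;
* affine readout `h : μ → ŷ`.

Training minimizes

```
L = L_rec + β · L_KL + α · L_dec
L_rec  = Poisson NLL of the raw counts given g(z),    z = μ + σ ⊙ ε
L_KL   = KL( N(μ_p, σ_p²) ‖ N(μ, σ²) )
L_dec  = ½ [ MSE(h(μ), y) + MSE(h(μ_r), y) ],   μ_r from f(g(z))
```

with the same `f` and `h` used for both decoding paths. `α` sets the
trade-off that operationally *defines* "behaviorally relevant": larger `α`
favors decodability, smaller `α` favors reconstruction. After training, the
relevant signal is `x_r = g(μ)` (posterior mean, no sampling) and the
irrelevant signal is the exact residual `x − x_r`. The weight `α` is chosen
by sweeping a grid and maximizing `0.75·D_re + 0.25·(1 − D_ir)`, where
`D_re`/`D_ir` are validation decoding R² of the relevant/irrelevant
partitions.

Because real recordings carry no ground truth, the package ships a synthetic
generator (`simulate_synthetic_dataset()`): center-out kinematics drive a
known encoder with nine strongly linearly tuned neurons (linear tuning
R² > 0.1) and three weakly tuned neurons (R² < 0.01, purely nonlinear
direction harmonics), and white Gaussian noise is added at an exactly
realized 7 dB signal-to-noise ratio. Reference decoders (least-squares
Kalman filter; a 300/100-unit ReLU network regressor) and a 5-fold
trial-level cross-validation harness support every decoding claim, and the
analysis suite covers preferred-direction deviation, Fano factors, PCA
variance structure, the subspace alignment index, variance composition,
correlation-matrix reordering, neuron-dropout and cumulative-PC decoding
curves, and speed-region improvement ratios.

## Worked example

```r
library(dvaer)

sds <- simulate_synthetic_dataset(seed = 1)   # 200 trials, 12 neurons
ds  <- sds$dataset
realized_snr_db(sds)
#> [1] 7

split <- make_folds(ds, k = 5, seed = 1)
fit <- train_dvae(ds, split, experiment = 1,
                  config = dvae_config(max_epochs = 50, seed = 1))
dec <- distill(fit$model, ds)

# similarity to the known ground-truth relevant signals
mean(per_neuron_similarity(dec$relevant, sds$ground_truth_relevant))
#> [1] -4.222635
mean(per_neuron_similarity(dec$raw,      sds$ground_truth_relevant))
#> [1] -6.56987

# decodability of each partition (network decoder, 5-fold CV)
for (sig in c("raw", "relevant", "irrelevant")) {
  print(cross_validated_decoding(dec[[sig]], ds$kinematics, split,
                                 ds$trial_id, decoder = "ann", seed = 2,
                                 signal = sig))
}
#> <decoding_scores> ANN on raw: R2 = 0.461 +/- 0.016 (5 folds)
#> <decoding_scores> ANN on relevant: R2 = 0.489 +/- 0.040 (5 folds)
#> <decoding_scores> ANN on irrelevant: R2 = 0.069 +/- 0.024 (5 folds)

# the weakly tuned neurons are undecodable by a linear fit on raw signals
tun <- cosine_tuning_fit(ds$counts, ds$kinematics)
round(tun$r_squared[sds$neuron_labels == "small"], 4)
#> [1] 2e-04 2e-04 1e-04
```

Reading the numbers: the 7 dB noise is heavy relative to the modulated part
of these low-rate neurons, so per-neuron similarity of the *raw* signals to
the ground truth is strongly negative (−6.57); distillation removes enough
noise to improve it markedly (−4.22) while the relevant partition decodes
velocity slightly *better* than the raw signals (0.489 vs 0.461) and the
residual carries little information (0.069). The weakly tuned neurons'
linear R² stays far below the 0.03 level after noise, as designed. The
training run takes roughly a minute on one CPU (early stopping usually ends
it near epoch 40).

`autoplot()` methods exist for tuning fits, α sweeps, subspace reports and
variance compositions; `tidy()`/`glance()` give tibble views of fitted
objects. A thin command-line wrapper with `synth`, `preprocess`, `train`,
`distill`, `decode`, `select-alpha` and `analyze` subcommands lives at
`inst/cli/dvaer.R` and exchanges data as CSV pairs with a JSON sidecar.

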