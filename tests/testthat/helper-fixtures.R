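# Shared fixtures, all generated in code at test time.

# small random trialed dataset
tiny_dataset <- function(n_trials = 6, bins = 10, n_neurons = 4, seed = 1) {
  set.seed(seed)
  n <- n_trials * bins
  binned_dataset(
    matrix(rpois(n * n_neurons, 2), n, n_neurons),
    cbind(rnorm(n), rnorm(n)),
    bin_width = 0.1,
    trial_id = rep(seq_len(n_trials), each = bins)
  )
}

# a small synthetic ground-truth dataset (cheaper than the default design)
small_synth <- function(seed = 1, n_trials = 40, bins = 12) {
  simulate_synthetic_dataset(n_trials = n_trials, bins_per_trial = bins,
                             seed = seed)
}

# compact d-VAE configuration for fast training tests
tiny_config <- function(...) {
  defaults <- list(latent_dim = 4L, encoder_widths = c(16L, 8L),
                   prior_width = 8L, batch_size = 64L, max_epochs = 15L)
  args <- utils::modifyList(defaults, list(...))
  do.call(dvae_config, args)
}

expect_perm <- function(x, n) {
  expect_setequal(x, seq_len(n))
  expect_equal(length(x), n)
}
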