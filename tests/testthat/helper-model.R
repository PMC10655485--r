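# Shared fitted-model fixtures, built once per test run.
#
# toy_fit(): small 3-tissue cohort and model, for fast contract tests.
# cohort_fit(): the 5-tissue validation study (500 training + 100 held-out
#   samples, reduced architecture) shared by the recovery and DE tests.

toy_fixture_cache <- new.env(parent = emptyenv())

toy_fit <- function() {
  if (!is.null(toy_fixture_cache$toy)) return(toy_fixture_cache$toy)
  sim <- simulate_cohort(n_tissues = 3, genes = 80, samples_per_tissue = 30,
                         latent_dim = 3, seed = 71)
  fit <- dgd(sim$counts, tissues = sim$truth$tissue,
             latent_dim = 3, n_components = 5, hidden = c(16, 32),
             prior = dgd_prior(spread = 3),
             control = dgd_control(epochs = 80, batch_size = 32,
                                   lr_decoder = 5e-4, lr_representation = 0.03,
                                   lr_gmm = 0.05, lr_dispersion = 1e-3,
                                   grad_clip = 10),
             seed = 72)
  toy_fixture_cache$toy <- list(sim = sim, fit = fit)
  toy_fixture_cache$toy
}

cohort_fit <- function() {
  if (!is.null(toy_fixture_cache$cohort)) return(toy_fixture_cache$cohort)
  sim <- simulate_cohort(n_tissues = 5, genes = 200, samples_per_tissue = 120,
                         latent_dim = 5, seed = 81)
  train_idx <- which(seq_len(600) %% 6 != 0)   # 100 per tissue train
  hold_idx <- which(seq_len(600) %% 6 == 0)    # 20 per tissue held out
  fit <- dgd(sim$counts[train_idx, ], tissues = sim$truth$tissue[train_idx],
             latent_dim = 5, n_components = 8, hidden = c(32, 64),
             prior = dgd_prior(spread = 3),
             control = dgd_control(epochs = 150, batch_size = 32,
                                   lr_decoder = 5e-4, lr_representation = 0.03,
                                   lr_gmm = 0.05, lr_dispersion = 1e-3,
                                   grad_clip = 10),
             seed = 82)
  toy_fixture_cache$cohort <- list(sim = sim, fit = fit,
                                   train_idx = train_idx, hold_idx = hold_idx)
  toy_fixture_cache$cohort
}
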