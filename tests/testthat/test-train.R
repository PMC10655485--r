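test_that("initialization matches the published starting state", {
  obj <- dgd_init(100, 10, seed = 51)            # default architecture
  expect_equal(obj$representations, matrix(0, 10, 50))
  expect_equal(exp(obj$log_r), rep(2, 100))
  expect_equal(dim(obj$gmm$means), c(45, 50))
  # component means start inside the softball support
  expect_true(all(sqrt(rowSums(obj$gmm$means^2)) <= obj$prior$spread))
  # same seed, same parameters
  obj2 <- dgd_init(100, 10, seed = 51)
  expect_identical(obj2$decoder, obj$decoder)
  expect_identical(obj2$gmm, obj$gmm)
  expect_error(dgd_init(0, 5), ">= 1")
})

test_that("zero learning rates make training the identity on parameters", {
  set.seed(52)
  counts <- matrix(rpois(30 * 25, 40), 30, 25)
  obj <- dgd_init(25, 30, latent_dim = 2, n_components = 3, hidden = c(6), seed = 53)
  # gradient training only: the post-fit estimation steps (dispersion
  # refit, consolidation, revival) are separate and switched off
  ctl <- dgd_control(epochs = 1, batch_size = 10, lr_decoder = 0,
                     lr_representation = 0, lr_gmm = 0, lr_dispersion = 0,
                     revive_every = 0, dispersion_refit = FALSE,
                     consolidate = 0)
  fit <- dgd_train(obj, counts, ctl)
  expect_identical(fit$decoder$W, obj$decoder$W)
  expect_identical(fit$gmm$means, obj$gmm$means)
  expect_identical(fit$log_r, obj$log_r)
  expect_identical(fit$representations, obj$representations)
  expect_equal(nrow(fit$loss), 1)
})

test_that("training is bit-reproducible under a fixed seed", {
  sim <- simulate_cohort(n_tissues = 2, genes = 30, samples_per_tissue = 15,
                         latent_dim = 2, seed = 54)
  ctl <- dgd_control(epochs = 5, batch_size = 10)
  f1 <- dgd(sim$counts, latent_dim = 2, n_components = 3, hidden = c(8),
            control = ctl, seed = 55)
  f2 <- dgd(sim$counts, latent_dim = 2, n_components = 3, hidden = c(8),
            control = ctl, seed = 55)
  expect_identical(f1$loss, f2$loss)
  expect_identical(f1$representations, f2$representations)
  expect_identical(f1$decoder, f2$decoder)
})

test_that("the loss descends on fittable synthetic data", {
  fit <- toy_fit()$fit
  loss <- fit$loss$total
  expect_lt(loss[length(loss)], loss[1])
  # monotone on a 10-epoch moving average
  ma <- stats::filter(loss, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) < 0.05 * abs(ma[-length(ma)])))
  expect_lt(mean(diff(ma) > 0), 0.2)
})

test_that("constraints hold after training", {
  fit <- toy_fit()$fit
  expect_true(all(exp(fit$log_r) > 0))
  w <- gmm_weights(fit$gmm)
  expect_true(all(w > 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(is.finite(fit$representations)))
  expect_true(all(is.finite(fit$loss$total)))
})

test_that("trained components recover the tissue structure", {
  cf <- cohort_fit()
  comp <- assign_component(cf$fit$representations, cf$fit$gmm)
  ari <- adjusted_rand(comp, cf$sim$truth$tissue[cf$train_idx])
  expect_gte(ari, 0.9)
  # association matrix: majority entry >= 90% in at least 4 of 5 tissues
  assoc <- association_matrix(comp, cf$sim$truth$tissue[cf$train_idx])
  maj_pct <- apply(assoc$percent, 2, max)
  tis_best <- tapply(maj_pct, assoc$majority, max)
  expect_gte(sum(tis_best >= 90), 4)
})
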