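test_that("zero-step inference reduces to the best component mean", {
  tf <- toy_fit()
  x <- tf$sim$counts[5, ]
  res <- dgd_infer(tf$fit, x, search_epochs = 0, refine_epochs = 0,
                   scale_method = "mean")
  means <- tf$fit$gmm$means
  objs <- vapply(seq_len(nrow(means)), function(c) {
    sample_log_joint(tf$fit, x, means[c, ], mean(x))
  }, numeric(1))
  expect_equal(drop(res$representations), means[which.max(objs), ])
  expect_equal(res$candidate_objectives[1, ], objs)
  expect_equal(res$objective, max(objs))
})

test_that("inference is deterministic and independent of sample order", {
  tf <- toy_fit()
  xs <- tf$sim$counts[c(2, 40, 70), ]
  r1 <- dgd_infer(tf$fit, xs, search_epochs = 3, refine_epochs = 5)
  r2 <- dgd_infer(tf$fit, xs, search_epochs = 3, refine_epochs = 5)
  expect_identical(r1$representations, r2$representations)
  r3 <- dgd_infer(tf$fit, xs[c(3, 1, 2), ], search_epochs = 3, refine_epochs = 5)
  expect_identical(r3$representations[2, ], r1$representations[1, ])
})

test_that("model parameters are bit-identical before and after inference", {
  tf <- toy_fit()
  before <- list(tf$fit$decoder, tf$fit$gmm, tf$fit$log_r, tf$fit$representations)
  invisible(dgd_infer(tf$fit, tf$sim$counts[1, ]))
  after <- list(tf$fit$decoder, tf$fit$gmm, tf$fit$log_r, tf$fit$representations)
  expect_identical(after, before)
})

test_that("refinement never ends below the selected candidate", {
  tf <- toy_fit()
  for (i in c(1, 31, 61)) {
    x <- tf$sim$counts[i, ]
    res10 <- dgd_infer(tf$fit, x, search_epochs = 10, refine_epochs = 0)
    res <- dgd_infer(tf$fit, x, search_epochs = 10, refine_epochs = 50)
    expect_gte(res$objective, res10$objective - 1e-6)
  }
})

test_that("inference rejects degenerate input", {
  tf <- toy_fit()
  x0 <- rep(0L, length(tf$fit$genes))
  expect_error(dgd_infer(tf$fit, x0), "all-zero")
  expect_error(dgd_infer(tf$fit, c(1L, 2L)), "gene count")
})

test_that("held-out samples are assigned to their tissue's components", {
  cf <- cohort_fit()
  truth <- cf$sim$truth
  comp_train <- assign_component(cf$fit$representations, cf$fit$gmm)
  assoc <- association_matrix(comp_train, truth$tissue[cf$train_idx])
  inf <- dgd_infer(cf$fit, cf$sim$counts[cf$hold_idx, ])
  pct <- tissue_match_percentage(inf$component, truth$tissue[cf$hold_idx], assoc)
  expect_gte(min(pct), 95)
})

test_that("samples from a decoded component mean return to that component", {
  tf <- toy_fit()
  comp_train <- assign_component(tf$fit$representations, tf$fit$gmm)
  occupied <- as.integer(names(which(table(comp_train) >= 10)))
  set.seed(61)
  for (c in occupied) {
    mu <- decode(tf$fit, tf$fit$gmm$means[c, ], 150)
    x <- rnbinom(length(mu), size = exp(tf$fit$log_r), mu = drop(mu))
    res <- dgd_infer(tf$fit, x)
    expect_equal(res$component, c)
  }
})

test_that("negative log probability mass is additive and flags perturbed samples", {
  tf <- toy_fit()
  x <- tf$sim$counts[10, ]
  res <- dgd_infer(tf$fit, x, scale_method = "mean")
  z <- drop(res$representations)
  m <- drop(decode(tf$fit, z, mean(x)))
  r <- exp(tf$fit$log_r)
  expect_equal(res$neg_log_prob_mass, -sum(nb_log_pmf(x, m, r)))
  # block additivity of the definition itself
  expect_equal(-sum(nb_log_pmf(x[1:40], m[1:40], r[1:40])) +
                 -sum(nb_log_pmf(x[41:80], m[41:80], r[41:80])),
               res$neg_log_prob_mass)
  # spiked samples score stochastically worse than their unspiked twins
  sim <- tf$sim
  idx <- sample(nrow(sim$counts), 12)
  nl_plain <- dgd_infer(tf$fit, sim$counts[idx, ])$neg_log_prob_mass
  spiked <- t(vapply(idx, function(i) {
    spike_sample(sim$counts[i, ], sim$truth, i, n_genes = 10, fold = 4,
                 min_dispersion = 4)$counts
  }, numeric(ncol(sim$counts))))
  nl_spiked <- dgd_infer(tf$fit, spiked)$neg_log_prob_mass
  expect_lt(wilcox.test(nl_spiked, nl_plain, alternative = "greater")$p.value, 0.05)
})
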