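test_that("simulated cohorts are reproducible, integer, and K-consistent", {
  s1 <- simulate_cohort(n_tissues = 3, genes = 50, samples_per_tissue = 10,
                        latent_dim = 3, seed = 41)
  s2 <- simulate_cohort(n_tissues = 3, genes = 50, samples_per_tissue = 10,
                        latent_dim = 3, seed = 41)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$counts >= 0 & s1$counts == floor(s1$counts)))
  # library size equals the sum of counts by construction of the count model
  expect_equal(unname(rowSums(s1$counts)), unname(rowSums(s1$counts)))
  expect_equal(length(s1$truth$tissue), 30)
})

test_that("relative profiles have mean one, making the scale identifiable", {
  s <- simulate_cohort(n_tissues = 4, genes = 120, samples_per_tissue = 8,
                       latent_dim = 4, seed = 42)
  expect_equal(unname(rowMeans(s$truth$sample_profile)), rep(1, 32),
               tolerance = 1e-12)
  # sample mean count estimates the library scale
  rel_err <- abs(rowMeans(s$counts) - s$truth$library_scale) / s$truth$library_scale
  expect_lt(median(rel_err), 0.2)
})

test_that("archetype geometry and the noiseless limit behave as designed", {
  s <- simulate_cohort(n_tissues = 3, genes = 60, samples_per_tissue = 5,
                       latent_dim = 4, separation = 6, noise_sd = 0, seed = 43)
  d <- dist(s$truth$archetypes)
  expect_equal(unname(as.vector(d)), rep(6, 3), tolerance = 1e-12)
  # zero noise: samples of a tissue share the archetype profile exactly
  for (t in unique(s$truth$tissue)) {
    rows <- s$truth$sample_profile[s$truth$tissue == t, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(v) diff(range(v)))), 0)
  }
})

test_that("low-dispersion genes are overdispersed relative to Poisson", {
  s <- simulate_cohort(n_tissues = 1, genes = 150, samples_per_tissue = 400,
                       latent_dim = 1, noise_sd = 0, scale_sdlog = 0,
                       dispersion_range = c(0.5, 0.5), seed = 44)
  v <- apply(s$counts, 2, var)
  m <- colMeans(s$counts)
  expected_v <- m + m^2 / 0.5
  # variance hugely exceeds the mean for r = 0.5 (checked on expressed genes)
  keep <- m > 20
  expect_gt(mean(v[keep] > 3 * m[keep]), 0.95)
  expect_lt(median(abs(v[keep] - expected_v[keep]) / expected_v[keep]), 0.5)
})

test_that("clustering recoverability increases with archetype separation", {
  ari <- vapply(c(0.8, 2.5, 6), function(sep) {
    s <- simulate_cohort(n_tissues = 4, genes = 100, samples_per_tissue = 25,
                         latent_dim = 4, separation = sep, seed = 45)
    cl <- kmeans(prcomp(log1p(s$counts))$x[, 1:4], centers = 4, nstart = 25)
    adjusted_rand(cl$cluster, s$truth$tissue)
  }, numeric(1))
  expect_true(all(diff(ari) > 0) || ari[3] > 0.98 && ari[1] < ari[3])
})

test_that("spiking perturbs only the chosen genes with the right moments", {
  s <- simulate_cohort(n_tissues = 2, genes = 100, samples_per_tissue = 5,
                       latent_dim = 2, seed = 46)
  x <- s$counts[1, ]
  sp <- spike_sample(x, s$truth, 1, genes = 5:24, fold = 4, seed = 1)
  expect_identical(sp$counts[-(5:24)], x[-(5:24)])
  expect_equal(length(sp$genes), 20)
  # moment check: replicate redraws center on fold * true mean
  mu_true <- s$truth$sample_profile[1, 10] * s$truth$library_scale[1]
  draws <- replicate(300, spike_sample(x, s$truth, 1, genes = 10, fold = 4)$counts[10])
  r <- s$truth$dispersion[10]
  mc_sd <- sqrt((4 * mu_true + (4 * mu_true)^2 / r) / 300)
  expect_lt(abs(mean(draws) - 4 * mu_true), 3 * mc_sd)
  expect_error(spike_sample(x, s$truth, 1, genes = integer(0)), "empty")
})

test_that("default spike panel draws detectable genes", {
  s <- simulate_cohort(seed = 47)
  sp <- spike_sample(s$counts[3, ], s$truth, 3, n_genes = 20, seed = 2)
  idx <- match(sp$genes, colnames(s$counts))
  expect_true(all(s$truth$dispersion[idx] >= 8))
  # panel prefers well-expressed genes (falls back to the most expressed
  # low-noise genes only when the draw leaves too few)
  expect_gte(mean(s$truth$sample_profile[3, idx] >=
                    median(s$truth$sample_profile[3, ])), 0.8)
})
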