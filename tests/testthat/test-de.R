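test_that("exact p-value equals brute-force summation to 1e-12", {
  set.seed(21)
  for (i in 1:60) {
    r <- exp(runif(1, log(0.5), log(20)))
    m <- runif(1, 0.5, 300)
    K <- sample(20:1000, 1)
    x <- min(rnbinom(1, size = r, mu = m), K)
    expect_equal(nb_exact_pvalue(x, m, r, K), brute_force_pvalue(x, m, r, K),
                 tolerance = 1e-12)
  }
  # x at the mode with ample K: everything is counted
  expect_equal(nb_exact_pvalue(10, m = 10.4, r = 50, K = 10000), 1, tolerance = 1e-9)
  # spec'd spot value
  expect_equal(nb_exact_pvalue(0, 5, 2, 500), brute_force_pvalue(0, 5, 2, 500),
               tolerance = 1e-12)
})

test_that("exact p-value respects its domain contract", {
  expect_error(nb_exact_pvalue(501, 5, 2, 500), "library size")
  expect_error(nb_exact_pvalue(-1, 5, 2, 500), "non-negative")
  expect_error(nb_exact_pvalue(1, 0, 2, 500), "positive")
  p <- nb_exact_pvalue(c(0, 5, 40), 5, 2, 500)
  expect_true(all(p > 0 & p <= 1))
})

test_that("saturated grid equals the exact p-value exactly", {
  set.seed(22)
  for (i in 1:20) {
    m <- runif(1, 1, 100); r <- runif(1, 0.5, 10); K <- sample(50:400, 1)
    x <- min(rnbinom(1, size = r, mu = m), K)
    expect_identical(nb_grid_pvalue(x, m, r, K, grid_points = K + 1),
                     nb_exact_pvalue(x, m, r, K))
  }
})

test_that("grid p-value converges monotonically to the exact value", {
  K <- 1e6; m <- 1000; r <- 2; x <- 2000
  exact <- nb_exact_pvalue(x, m, r, K)
  errs <- vapply(c(1e2, 1e3, 1e4), function(g) {
    abs(nb_grid_pvalue(x, m, r, K, grid_points = g) - exact)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("two-sided p-value is monotone away from the mode", {
  m <- 50; r <- 5; K <- 5000
  mode <- floor(m * (r - 1) / r)
  up <- nb_exact_pvalue(mode:(mode + 100), m, r, K)
  down <- nb_exact_pvalue(mode:0, m, r, K)
  expect_true(all(diff(up) <= 1e-14))
  expect_true(all(diff(down) <= 1e-14))
})

test_that("null draws give conservative, near-uniform p-values", {
  set.seed(23)
  m <- 50; r <- 2; K <- 1e4; n <- 4000
  x <- pmin(rnbinom(n, size = r, mu = m), K)
  p <- nb_exact_pvalue(x, m, r, K)
  rate <- mean(p < 0.05)
  mc_sd <- sqrt(0.05 * 0.95 / n)
  expect_lte(rate, 0.05 + 3 * mc_sd)
  # discrete test: empirical CDF below the uniform CDF (conservative)
  grid <- seq(0.01, 1, by = 0.01)
  ecdf_p <- ecdf(p)(grid)
  expect_true(all(ecdf_p <= grid + 3 * sqrt(grid * (1 - grid) / n) + 1e-12))
})

test_that("log2 fold change identities hold", {
  expect_equal(log2_fold_change(7, 7), 0)
  expect_equal(log2_fold_change(4 * 5 + 3, 5), 2)  # x+1 = 4 (m+1)
  expect_equal(log2_fold_change(0, 1), -1)
  expect_equal(log2_fold_change(10, 10, pseudocount = 0.5), 0)
})

test_that("BH adjustment behaves as the step-up rule", {
  # constant vector is a fixed point
  expect_equal(p.adjust(rep(0.02, 5), "BH"), rep(0.02, 5))
  # hand-executed step-up on three points
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_equal(p.adjust(0.04, "BH"), 0.04)
})

test_that("enrichment score follows its definition and set semantics", {
  expect_equal(enrichment_score(paste0("g", 1:20),
                                paste0("g", c(1:5, 101:145)), 1000), 5)
  # significant = universe -> no enrichment by construction
  uni <- paste0("g", 1:100)
  expect_equal(enrichment_score(uni, uni[1:10], 100), 1)
  # relabeling invariance: only set identity matters
  expect_equal(enrichment_score(c("b", "a"), c("a", "c"), 10),
               enrichment_score(c("a", "b"), c("c", "a"), 10))
  expect_warning(es <- enrichment_score(character(0), "a", 10), "undefined")
  expect_true(is.na(es))
  # permutation null: mean ES over random draws is ~1
  set.seed(24)
  total <- 500; markers <- paste0("g", sample(total, 40))
  es <- replicate(2000, enrichment_score(paste0("g", sample(total, 25)), markers, total))
  mc_sd <- sd(es) / sqrt(length(es))
  expect_lt(abs(mean(es) - 1), 3 * mc_sd + 0.02)
})
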