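test_that("softball density is radial, monotone, and matches its formula", {
  spread <- 7; sharp <- 10; D <- 5
  # strictly higher at the center than at the boundary
  z_bound <- c(spread, rep(0, D - 1))
  expect_gt(softball_log_density(rep(0, D), spread, sharp),
            softball_log_density(z_bound, spread, sharp))
  # mollifier equals -log(2) exactly at the boundary radius
  norm_const <- -(D / 2) * log(pi) + lgamma(D / 2 + 1) - D * log(spread)
  expect_equal(softball_log_density(z_bound, spread, sharp),
               norm_const - log(2), tolerance = 1e-12)
  # direct formula at twice the radius
  z2 <- c(2 * spread, rep(0, D - 1))
  expect_equal(softball_log_density(z2, spread, sharp),
               norm_const - log1p(exp(sharp * (2 - 1))), tolerance = 1e-12)
  # rotation invariance: depends on z only through its norm
  set.seed(3)
  z <- rnorm(D)
  q <- qr.Q(qr(matrix(rnorm(D * D), D)))
  expect_equal(softball_log_density(z, spread, sharp),
               softball_log_density(drop(q %*% z), spread, sharp), tolerance = 1e-12)
})

test_that("softball density integrates to ~1 in low dimension", {
  # 1-D check by quadrature: the mollified ball is a proper density
  f <- function(t) exp(softball_log_density(matrix(t, ncol = 1), 3, 10))
  total <- integrate(f, -20, 20, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-3)
})

test_that("gmm_log_density matches closed forms and the naive-sum oracle", {
  D <- 4
  std <- dgd_gmm(means = matrix(0, 1, D))
  expect_equal(gmm_log_density(rep(0, D), std), -(D / 2) * log(2 * pi))
  # two well-separated equal-weight components: log(1/2) + mode density
  sep <- dgd_gmm(means = rbind(rep(50, D), rep(-50, D)))
  expect_equal(gmm_log_density(rep(50, D), sep),
               log(0.5) - (D / 2) * log(2 * pi), tolerance = 1e-10)
  # random mixtures against direct summation
  set.seed(5)
  for (i in 1:20) {
    g <- random_gmm(3, 4)
    z <- rnorm(4, sd = 3)
    expect_equal(gmm_log_density(z, g),
                 naive_gmm_log_density(z, g$means, g$beta, g$logits),
                 tolerance = 1e-10)
  }
})

test_that("gmm_log_density is finite far outside the mixture support", {
  g <- random_gmm(3, 8)
  z <- rep(1000 / sqrt(8), 8)
  expect_true(is.finite(gmm_log_density(z, g)))
  expect_true(is.finite(softball_log_density(z, 7, 10)))
})

test_that("parameter log prior decomposes and peaks at the prior modes", {
  set.seed(9)
  C <- 3; D <- 2
  pr <- dgd_prior()
  at_mode <- dgd_gmm(means = matrix(0, C, D),
                     beta = matrix(pr$beta_mean, C, D), logits = rep(0, C))
  base <- gmm_log_prior(at_mode, pr)
  # +1 sd on one beta entry drops the total by exactly 1/2
  pert <- dgd_gmm(means = matrix(0, C, D),
                  beta = matrix(pr$beta_mean, C, D) + matrix(c(pr$beta_sd, rep(0, C * D - 1)), C, D),
                  logits = rep(0, C))
  expect_equal(gmm_log_prior(pert, pr) - base, -0.5, tolerance = 1e-12)
  # term-by-term oracle on a random model
  g <- random_gmm(C, D)
  w <- gmm_weights(g)
  expected <- sum(softball_log_density(g$means, pr$spread, pr$sharpness)) +
    sum(dnorm(g$beta, pr$beta_mean, pr$beta_sd, log = TRUE)) +
    lgamma(C * pr$alpha) - C * lgamma(pr$alpha) + (pr$alpha - 1) * sum(log(w))
  expect_equal(gmm_log_prior(g, pr), expected, tolerance = 1e-12)
})

test_that("component assignment agrees with naive density comparison and tie rule", {
  D <- 3
  sep <- dgd_gmm(means = rbind(rep(10, D), rep(0, D), rep(-10, D), rep(20, D)))
  expect_equal(assign_component(rep(-10, D), sep), 3L)
  # symmetric two-component mixture, equidistant point -> lowest index
  sym <- dgd_gmm(means = rbind(c(1, 0), c(-1, 0)))
  expect_equal(assign_component(c(0, 5), sym), 1L)
  set.seed(11)
  for (i in 1:20) {
    g <- random_gmm(4, 3)
    z <- rnorm(3, sd = 2)
    naive <- which.max(vapply(seq_len(4), function(c) {
      log(gmm_weights(g)[c]) + sum(dnorm(z, g$means[c, ], sqrt(exp(-g$beta[c, ])), log = TRUE))
    }, numeric(1)))
    expect_equal(assign_component(z, g), naive)
  }
})
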