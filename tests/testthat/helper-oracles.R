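# Independent oracles used across the suite. These deliberately take the
# naive route (direct summation, dense evaluation) so they share no code
# path with the implementation they check.

# brute-force two-tailed NB p-value: literal sum over k = 0..K
brute_force_pvalue <- function(x, m, r, K) {
  d <- dnbinom(0:K, size = r, mu = m)
  sum(d[d <= d[x + 1]])
}

# naive GMM log density: direct weighted sum of dnorm products
naive_gmm_log_density <- function(z, means, beta, logits) {
  w <- exp(logits) / sum(exp(logits))
  dens <- sum(vapply(seq_len(nrow(means)), function(c) {
    w[c] * prod(dnorm(z, means[c, ], sqrt(exp(-beta[c, ]))))
  }, numeric(1)))
  log(dens)
}

# random small mixture for oracle comparisons
random_gmm <- function(C, D) {
  dgd_gmm(means = matrix(rnorm(C * D, sd = 2), C, D),
          beta = matrix(rnorm(C * D, 1, 0.5), C, D),
          logits = rnorm(C))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
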