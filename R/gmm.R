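#' Gaussian mixture parameters for the latent space
#'
#' Container for the mixture that parameterizes the representation space:
#' component means (C x D), the negative natural log of the diagonal
#' covariances (C x D, so per-dimension variance is `exp(-beta)`), and
#' unconstrained mixture-weight logits mapped to the simplex by softmax.
#'
#' @param means Numeric C x D matrix of component means.
#' @param beta Numeric C x D matrix; variance of component c, dimension d is
#'   `exp(-beta[c, d])`.
#' @param logits Numeric length-C vector of mixture-weight logits.
#' @return An object of class `"dgd_gmm"`.
#' @export
dgd_gmm <- function(means, beta = NULL, logits = NULL) {
  means <- as.matrix(means)
  if (is.null(beta)) beta <- matrix(0, nrow(means), ncol(means))
  beta <- as.matrix(beta)
  if (is.null(logits)) logits <- rep(0, nrow(means))
  if (!all(dim(means) == dim(beta))) stop_dgd("'means' and 'beta' must have equal dimensions")
  if (length(logits) != nrow(means)) stop_dgd("'logits' must have one entry per component")
  if (any(!is.finite(means)) || any(!is.finite(beta)) || any(!is.finite(logits)))
    stop_dgd("GMM parameters must be finite")
  structure(list(means = means, beta = beta, logits = logits,
                 C = nrow(means), D = ncol(means)),
            class = "dgd_gmm")
}

#' Mixture weights of a latent GMM
#'
#' @param gmm A [dgd_gmm()] object.
#' @return Length-C positive vector summing to one.
#' @export
gmm_weights <- function(gmm) softmax(gmm$logits)

# N x C matrix of log w_c + log N(z_i; mu_c, diag(exp(-beta_c)))
gmm_component_log_density <- function(z, gmm) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  if (ncol(z) != gmm$D) stop_dgd("latent dimension mismatch: z has ", ncol(z),
                                 " columns, GMM expects ", gmm$D)
  logw <- log(gmm_weights(gmm))
  out <- matrix(0, nrow(z), gmm$C)
  for (c in seq_len(gmm$C)) {
    dev2 <- sweep(z, 2L, gmm$means[c, ])^2
    prec <- exp(gmm$beta[c, ])                       # 1 / variance
    out[, c] <- logw[c] - 0.5 * gmm$D * log(2 * pi) +
      0.5 * sum(gmm$beta[c, ]) -
      0.5 * drop(dev2 %*% prec)
  }
  out
}

#' Log density of latent vectors under the mixture
#'
#' Computes \eqn{\log \sum_c w_c N(z; \mu_c, diag(e^{-\beta_c}))} with
#' log-sum-exp stabilization, so the result is finite for \eqn{\|z\|} far
#' outside the support of all components.
#'
#' @param z Latent vector or matrix of row vectors (columns = dimension D).
#' @param gmm A [dgd_gmm()] object.
#' @return One log density per row of `z`.
#' @export
gmm_log_density <- function(z, gmm) {
  logsumexp_rows(gmm_component_log_density(z, gmm))
}

# responsibilities gamma_{ic} (rows sum to 1) for gradient computations
gmm_responsibilities <- function(z, gmm) {
  lcd <- gmm_component_log_density(z, gmm)
  g <- exp(lcd - logsumexp_rows(lcd))
  g
}

# d log p(z) / d z, one row per row of z
gmm_grad_z <- function(z, gmm) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  gam <- gmm_responsibilities(z, gmm)
  out <- matrix(0, nrow(z), ncol(z))
  for (c in seq_len(gmm$C)) {
    prec <- exp(gmm$beta[c, ])
    dev <- sweep(z, 2L, gmm$means[c, ])
    out <- out - gam[, c] * sweep(dev, 2L, prec, `*`)
  }
  out
}

# gradients of sum_i log p(z_i) w.r.t. GMM parameters
gmm_grad_params <- function(z, gmm) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  gam <- gmm_responsibilities(z, gmm)
  w <- gmm_weights(gmm)
  g_means <- matrix(0, gmm$C, gmm$D)
  g_beta <- matrix(0, gmm$C, gmm$D)
  for (c in seq_len(gmm$C)) {
    prec <- exp(gmm$beta[c, ])
    dev <- sweep(z, 2L, gmm$means[c, ])
    g_means[c, ] <- colSums(gam[, c] * sweep(dev, 2L, prec, `*`))
    g_beta[c, ] <- colSums(gam[, c] * (0.5 - 0.5 * sweep(dev^2, 2L, prec, `*`)))
  }
  g_logits <- colSums(gam) - nrow(z) * w
  list(means = g_means, beta = g_beta, logits = g_logits)
}

#' Hyperparameters of the parameter priors
#'
#' Priors placed on the mixture parameters themselves: a softball prior
#' (radius `spread`, steepness `sharpness`) on each component mean, a
#' Gaussian on every entry of the negative-log covariance matrix `beta`,
#' and a symmetric Dirichlet on the mixture weights.
#'
#' @param spread,sharpness Softball prior on component means.
#' @param beta_mean,beta_sd Gaussian prior on each `beta[c, d]`.
#' @param alpha Shared Dirichlet concentration on mixture weights.
#' @return An object of class `"dgd_prior"`.
#' @export
dgd_prior <- function(spread = 7, sharpness = 10, beta_mean = 1, beta_sd = 1,
                      alpha = 5) {
  vals <- c(spread, sharpness, beta_sd, alpha)
  if (any(!is.finite(c(vals, beta_mean))) || any(vals <= 0))
    stop_dgd("prior hyperparameters must be finite and (except beta_mean) positive")
  structure(list(spread = spread, sharpness = sharpness,
                 beta_mean = beta_mean, beta_sd = beta_sd, alpha = alpha),
            class = "dgd_prior")
}

#' Log prior density of the mixture parameters
#'
#' Sum of the softball log density over component means, Gaussian log
#' density over every negative-log covariance entry, and Dirichlet log
#' density over the mixture weights.
#'
#' @param gmm A [dgd_gmm()] object.
#' @param prior A [dgd_prior()] object.
#' @return Scalar log prior density.
#' @export
gmm_log_prior <- function(gmm, prior = dgd_prior()) {
  w <- gmm_weights(gmm)
  sb <- sum(softball_log_density(gmm$means, prior$spread, prior$sharpness))
  gb <- sum(stats::dnorm(gmm$beta, prior$beta_mean, prior$beta_sd, log = TRUE))
  a <- prior$alpha
  dir <- lgamma(gmm$C * a) - gmm$C * lgamma(a) + (a - 1) * sum(log(w))
  sb + gb + dir
}

# gradients of gmm_log_prior w.r.t. means, beta, logits
gmm_grad_prior <- function(gmm, prior) {
  w <- gmm_weights(gmm)
  list(means = softball_grad(gmm$means, prior$spread, prior$sharpness),
       beta = -(gmm$beta - prior$beta_mean) / prior$beta_sd^2,
       logits = (prior$alpha - 1) * (1 - gmm$C * w))
}

#' Hard assignment of a representation to a mixture component
#'
#' Returns the component with the highest weighted density
#' \eqn{\log w_c + \log N(z; \mu_c, \Sigma_c)}; this is the unsupervised
#' "tissue classifier" used throughout evaluation. Ties are broken toward
#' the lowest component index.
#'
#' @param z Latent vector or matrix of row vectors.
#' @param gmm A [dgd_gmm()] object.
#' @return Integer component index (1-based), one per row of `z`.
#' @export
assign_component <- function(z, gmm) {
  lcd <- gmm_component_log_density(z, gmm)
  apply(lcd, 1L, which.max)
}
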