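#' @export
print.dgd <- function(x, ...) {
  cat("Deep generative decoder", if (isTRUE(x$trained)) "(fitted)" else "(untrained)", "\n")
  cat("  genes:", length(x$genes),
      "  latent dim:", x$latent_dim,
      "  mixture components:", x$n_components, "\n")
  cat("  decoder:", paste(c(x$latent_dim, x$hidden, length(x$genes)), collapse = " -> "),
      "(rectified)\n")
  if (isTRUE(x$trained)) {
    cat("  samples:", nrow(x$representations), "\n")
    cat(sprintf("  final loss: %.4f (epoch %d)\n",
                x$loss$total[nrow(x$loss)], nrow(x$loss)))
  }
  invisible(x)
}

#' Summarize a fitted deep generative decoder
#'
#' Reports the loss trajectory, mixture occupancy (samples per component by
#' hard assignment) and, when tissue labels were supplied, the
#' tissue-component association matrix.
#'
#' @param object A fitted [dgd] model.
#' @param ... Unused.
#' @return An object of class `"summary.dgd"`.
#' @export
summary.dgd <- function(object, ...) {
  if (!isTRUE(object$trained)) stop_dgd("model is not fitted")
  comp <- assign_component(object$representations, object$gmm)
  assoc <- if (!is.null(object$tissues)) association_matrix(comp, object$tissues)
  structure(list(loss = object$loss, component = comp, association = assoc,
                 weights = gmm_weights(object$gmm),
                 dispersion = exp(object$log_r), model = object),
            class = "summary.dgd")
}

#' @export
print.summary.dgd <- function(x, ...) {
  print(x$model)
  occ <- table(factor(x$component, levels = seq_len(x$model$n_components)))
  cat("  component occupancy:", paste(occ, collapse = " "), "\n")
  cat(sprintf("  dispersion range: %.3g - %.3g\n",
              min(x$dispersion), max(x$dispersion)))
  if (!is.null(x$association)) print(x$association)
  invisible(x)
}

#' Extract model parameters
#'
#' @param object A [dgd] model.
#' @param ... Unused.
#' @return List with `means`, `beta`, `logits`, `weights` (mixture),
#'   `dispersion` (gene-wise NB) and `decoder` (weights and biases).
#' @export
coef.dgd <- function(object, ...) {
  list(means = object$gmm$means, beta = object$gmm$beta,
       logits = object$gmm$logits, weights = gmm_weights(object$gmm),
       dispersion = stats::setNames(exp(object$log_r), object$genes),
       decoder = object$decoder[c("W", "b")])
}

#' Predict from a fitted deep generative decoder
#'
#' @param object A fitted [dgd] model.
#' @param newdata Optional count matrix (samples x genes). When absent,
#'   predictions are made for the training samples at their learned
#'   representations.
#' @param type `"mean"` for decoded NB means, `"representation"` for
#'   inferred latent vectors, `"component"` for hard mixture assignments.
#' @param ... Passed to [dgd_infer()] when inference is needed.
#' @return Matrix of means, matrix of representations, or integer vector of
#'   components.
#' @export
predict.dgd <- function(object, newdata = NULL,
                        type = c("mean", "representation", "component"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    Z <- object$representations
    scale <- object$sample_scale
    comp <- assign_component(Z, object$gmm)
  } else {
    counts <- as_count_matrix(newdata)
    inf <- dgd_infer(object, counts, ...)
    Z <- inf$representations
    scale <- rowMeans(counts)
    comp <- inf$component
  }
  switch(type,
         mean = decode(object, Z, scale),
         representation = Z,
         component = comp)
}

#' Pearson residuals under the fitted NB model
#'
#' `(x - m) / sqrt(m + m^2 / r)` at the decoded means of the training
#' representations.
#'
#' @param object A fitted [dgd] model.
#' @param x The training count matrix the model was fitted to.
#' @param ... Unused.
#' @return Samples x genes matrix of Pearson residuals.
#' @export
residuals.dgd <- function(object, x, ...) {
  counts <- as_count_matrix(x)
  m <- decode(object, object$representations, object$sample_scale)
  r <- matrix(exp(object$log_r), nrow(m), ncol(m), byrow = TRUE)
  (counts - m) / sqrt(m + m^2 / r)
}

#' Simulate count matrices from a fitted model
#'
#' Draws NB counts at the decoded means of representations — by default
#' the training representations with their sample scales, i.e. posterior
#' predictive replicates of the cohort.
#'
#' @param object A fitted [dgd] model.
#' @param nsim Number of replicate matrices.
#' @param seed Optional RNG seed.
#' @param representations,sample_scale Optional latent vectors (rows) and
#'   matching positive scales to decode instead of the training ones.
#' @param ... Unused.
#' @return A list of `nsim` samples x genes count matrices.
#' @export
simulate.dgd <- function(object, nsim = 1, seed = NULL,
                         representations = NULL, sample_scale = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  Z <- representations %||% object$representations
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = 1L)
  scale <- sample_scale %||% object$sample_scale
  m <- decode(object, Z, scale)
  r <- matrix(exp(object$log_r), nrow(m), ncol(m), byrow = TRUE)
  replicate(nsim, {
    out <- matrix(stats::rnbinom(length(m), size = r, mu = m), nrow(m), ncol(m))
    colnames(out) <- object$genes
    out
  }, simplify = FALSE)
}

#' Plot the latent space of a fitted model
#'
#' Two-dimensional principal component projection of the sample
#' representations, colored by tissue when labels are available, with
#' mixture component means overlaid as crosses.
#'
#' @param x A fitted [dgd] model.
#' @param ... Passed to [graphics::plot()].
#' @return The PCA rotation, invisibly.
#' @export
plot.dgd <- function(x, ...) {
  if (!isTRUE(x$trained)) stop_dgd("model is not fitted")
  pc <- stats::prcomp(x$representations, rank. = 2)
  col <- if (!is.null(x$tissues)) as.integer(factor(x$tissues)) else 1L
  graphics::plot(pc$x[, 1], pc$x[, 2], col = col, pch = 16,
                 xlab = "PC1", ylab = "PC2",
                 main = "Latent representations", ...)
  mu <- scale(x$gmm$means, center = pc$center, scale = FALSE) %*% pc$rotation
  graphics::points(mu[, 1], mu[, 2], pch = 3, cex = 1.5, lwd = 2)
  invisible(pc$rotation)
}
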