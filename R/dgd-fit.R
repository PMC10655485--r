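#' Training settings for a deep generative decoder
#'
#' Mirrors the published training recipe: Adam with betas (0.5, 0.9), no
#' weight decay, and one optimizer instance per parameter group. Decoder
#' weights use a small learning rate (1e-4); representations and mixture
#' parameters use 0.01. Gene-wise dispersions are distribution parameters
#' like the mixture's, and get their own instance at 0.01 (see the methods
#' vignette for the reasoning).
#'
#' @param epochs Number of passes over the cohort.
#' @param batch_size Samples per minibatch.
#' @param lr_decoder,lr_representation,lr_gmm,lr_dispersion Learning rates
#'   for the four parameter groups.
#' @param betas Adam moment-decay coefficients.
#' @param weight_decay L2 penalty on decoder weights (default 0, as trained).
#' @param revive_every Interval (in epochs) at which idle mixture
#'   components are reseeded at the representation the mixture currently
#'   explains worst; 0 disables. Revival is the usual empty-cluster device
#'   of mixture fitting and only runs during the first 70% of the epochs,
#'   leaving the final phase a pure joint optimization.
#' @param revive_share A component is idle when its share of the total
#'   responsibility mass falls below `revive_share / C` (i.e. the
#'   threshold is a fraction of the uniform share; redundant components
#'   stacked on one cluster fall under it, healthy ones do not).
#' @param grad_clip Elementwise bound on the reconstruction gradient with
#'   respect to each decoded mean (after batch scaling). The NB gradient
#'   k/m explodes when a rectified output approaches zero under a positive
#'   observed count; unclipped spikes poison the optimizer's second
#'   moments. 0 disables.
#' @param dispersion_refit After training, re-estimate each gene's
#'   dispersion by profile maximum likelihood at the fitted means
#'   (1-D optimization per gene). The gradient updates shape training,
#'   but their reach over a finite schedule is limited by the learning
#'   rate; the refit gives the likelihood-optimal dispersion given the
#'   decoder actually obtained, which keeps the downstream test
#'   calibrated. Disable with `FALSE`.
#' @param consolidate After training, component pairs whose mean
#'   separation is below this many pooled standard deviations are
#'   moment-matched and collapsed onto identical parameters (weights
#'   split evenly), so a population described twice is described once;
#'   the mixture density is preserved up to the pair's internal offset.
#'   0 disables.
#' @param verbose Print per-epoch losses while fitting.
#' @return An object of class `"dgd_control"`.
#' @export
dgd_control <- function(epochs = 200, batch_size = 256,
                        lr_decoder = 1e-4, lr_representation = 0.01,
                        lr_gmm = 0.01, lr_dispersion = 0.01,
                        betas = c(0.5, 0.9), weight_decay = 0,
                        revive_every = 10, revive_share = 0.5,
                        grad_clip = 1, dispersion_refit = TRUE,
                        consolidate = 2, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1,
            lr_decoder >= 0, lr_representation >= 0, lr_gmm >= 0,
            lr_dispersion >= 0, length(betas) == 2L, weight_decay >= 0,
            revive_every >= 0, revive_share >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_decoder = lr_decoder, lr_representation = lr_representation,
                 lr_gmm = lr_gmm, lr_dispersion = lr_dispersion,
                 betas = betas, weight_decay = weight_decay,
                 revive_every = as.integer(revive_every),
                 revive_share = revive_share, grad_clip = grad_clip,
                 dispersion_refit = isTRUE(dispersion_refit),
                 consolidate = consolidate, verbose = verbose),
            class = "dgd_control")
}

#' Initialize an untrained deep generative decoder
#'
#' Builds the model skeleton the fitter starts from: all-zero
#' representations, gene dispersions at `dispersion_init`, mixture means
#' drawn uniformly inside the softball support, unit variances, uniform
#' weights, and a fan-in uniform decoder initialization with positive biases
#' (so every rectified unit is initially active and receives gradient).
#'
#' @param gene_count Number of genes G.
#' @param n_samples Number of training samples N.
#' @param latent_dim Representation dimension D.
#' @param n_components Mixture components C.
#' @param hidden Hidden layer widths of the decoder.
#' @param dispersion_init Initial gene-wise NB dispersion.
#' @param beta_init Initial value for every negative-log covariance entry;
#'   defaults to `prior$beta_mean + 1.5`, i.e. components start narrower
#'   than the prior mode so that early responsibility competition is local
#'   and a single component cannot capture several nascent clusters.
#' @param mean_floor Positive floor added to decoded means so the NB pmf is
#'   defined where the output rectifier emits exact zeros.
#' @param prior A [dgd_prior()].
#' @param genes Optional gene identifiers (length `gene_count`).
#' @param seed Optional RNG seed for the parameter draws.
#' @return An object of class `"dgd"` (untrained; `$representations` all zero).
#' @export
dgd_init <- function(gene_count, n_samples, latent_dim = 50, n_components = 45,
                     hidden = c(500, 8000), dispersion_init = 2,
                     beta_init = NULL, mean_floor = 1e-10, prior = dgd_prior(),
                     genes = NULL, seed = NULL) {
  if (gene_count < 1 || n_samples < 1) stop_dgd("'gene_count' and 'n_samples' must be >= 1")
  if (dispersion_init <= 0) stop_dgd("'dispersion_init' must be positive")
  if (!is.null(seed)) set.seed(seed)
  genes <- genes %||% paste0("gene", seq_len(gene_count))
  if (length(genes) != gene_count) stop_dgd("'genes' must have length 'gene_count'")

  decoder <- decoder_init(c(latent_dim, hidden, gene_count))
  # component means uniform in the ball of radius `spread`
  dirs <- matrix(stats::rnorm(n_components * latent_dim), n_components, latent_dim)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  radii <- prior$spread * stats::runif(n_components)^(1 / latent_dim)
  beta_init <- beta_init %||% (prior$beta_mean + 1.5)
  gmm <- dgd_gmm(means = dirs * radii,
                 beta = matrix(beta_init, n_components, latent_dim),
                 logits = rep(0, n_components))
  structure(list(
    decoder = decoder,
    gmm = gmm,
    log_r = rep(log(dispersion_init), gene_count),
    prior = prior,
    genes = genes,
    latent_dim = as.integer(latent_dim),
    n_components = as.integer(n_components),
    hidden = hidden,
    mean_floor = mean_floor,
    representations = matrix(0, n_samples, latent_dim),
    sample_ids = NULL, tissues = NULL, sample_scale = NULL,
    loss = NULL, control = NULL, trained = FALSE
  ), class = "dgd")
}

# Collapse component pairs closer than `threshold` pooled standard
# deviations: the pair is replaced by two identical moment-matched
# components carrying half the pooled weight each (mixture reduction by
# moment matching; the density changes only by the pair's internal offset).
consolidate_components <- function(gmm, threshold) {
  C <- gmm$C
  w <- softmax(gmm$logits)
  vars <- exp(-gmm$beta)
  # adjacency under the pooled-sd distance, then connected components
  adj <- matrix(FALSE, C, C)
  for (i in seq_len(C - 1L)) {
    for (j in seq(i + 1L, C)) {
      d2 <- sum((gmm$means[i, ] - gmm$means[j, ])^2 / (vars[i, ] + vars[j, ]))
      adj[i, j] <- adj[j, i] <- sqrt(d2) < threshold
    }
  }
  group <- integer(C)
  g <- 0L
  for (s in seq_len(C)) {
    if (group[s] > 0L) next
    g <- g + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (group[v] > 0L) next
      group[v] <- g
      queue <- c(queue, which(adj[v, ] & group == 0L))
    }
  }
  logits <- log(w)
  for (k in seq_len(g)) {
    members <- which(group == k)
    if (length(members) < 2L) next
    wm <- w[members]; ws <- sum(wm)
    mu <- colSums(wm * gmm$means[members, , drop = FALSE]) / ws
    m2 <- colSums(wm * (vars[members, , drop = FALSE] +
                          gmm$means[members, , drop = FALSE]^2)) / ws - mu^2
    m2 <- pmax(m2, 1e-12)
    for (i in members) {
      gmm$means[i, ] <- mu
      gmm$beta[i, ] <- -log(m2)
    }
    logits[members] <- log(ws / length(members))
  }
  gmm$logits <- logits - mean(logits)
  gmm
}

#' Decode representations into gene-wise negative binomial means
#'
#' Passes latent vectors through the decoder (rectified output) and scales
#' by each sample's mean count across genes, then lifts by the positive
#' mean floor: `m = max(0, f(z)) * sample_scale + mean_floor`.
#'
#' @param object A fitted or initialized [dgd] model.
#' @param z Latent vector, or matrix with one representation per row.
#' @param sample_scale Positive scalar or per-row vector: the sample's mean
#'   count across genes.
#' @return Matrix of NB means (rows = rows of `z`, columns = genes).
#' @export
decode <- function(object, z, sample_scale) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  if (ncol(z) != object$latent_dim) stop_dgd("latent dimension mismatch")
  if (any(sample_scale <= 0) || any(!is.finite(sample_scale)))
    stop_dgd("'sample_scale' must be positive")
  y <- decoder_forward(object$decoder, z)$output
  y * sample_scale + object$mean_floor
}

#' Log joint of one sample's counts and its representation
#'
#' The per-sample training objective: the NB reconstruction log likelihood
#' of the counts at the decoded means plus the mixture log density of the
#' representation.
#'
#' @param object A [dgd] model.
#' @param x Integer count vector over the model's genes.
#' @param z Latent vector.
#' @param sample_scale The sample's mean count (defaults to `mean(x)`).
#' @return Scalar log joint density.
#' @export
sample_log_joint <- function(object, x, z, sample_scale = mean(x)) {
  if (length(x) != length(object$genes)) stop_dgd("'x' length must equal gene count")
  m <- decode(object, z, sample_scale)
  sum(nb_log_pmf(x, drop(m), exp(object$log_r))) +
    drop(gmm_log_density(z, object$gmm))
}

# validate and coerce a samples x genes count matrix
as_count_matrix <- function(x) {
  if (inherits(x, "dgd_counts")) return(x$counts)
  x <- as.matrix(x)
  if (any(x < 0) || any(x != floor(x)) || any(!is.finite(x)))
    stop_dgd("counts must be finite non-negative integers")
  x
}

#' Fit a deep generative decoder to a count cohort
#'
#' Learns per-sample latent representations, a Gaussian-mixture latent
#' distribution, decoder weights, and gene-wise NB dispersions jointly by
#' maximum a posteriori gradient optimization. Every sample appears in
#' exactly one shuffled minibatch per epoch; four Adam instances update the
#' decoder, the representations, the mixture parameters and the dispersions.
#' The minimized objective per batch is the negative batch-mean of
#' [sample_log_joint()] minus the mixture parameter log prior scaled by
#' 1/(number of batches), so one epoch applies the prior with total weight 1.
#'
#' @param x Integer count matrix, samples in rows and genes in columns (or a
#'   `"dgd_counts"` object from [read_counts()]).
#' @param tissues Optional per-sample tissue labels (for summaries and
#'   evaluation; never used by the objective).
#' @param latent_dim,n_components,hidden,dispersion_init,mean_floor,prior
#'   Model architecture; see [dgd_init()].
#' @param control A [dgd_control()] with the optimization settings.
#' @param seed Optional seed making initialization, batch shuffling and
#'   therefore the whole fit reproducible.
#' @return An object of class `"dgd"`; see [dgd_init()] for the parameter
#'   fields. Adds `$representations` (N x D), `$loss` (per-epoch totals and
#'   reconstruction / latent / prior terms), `$sample_scale`, `$sample_ids`,
#'   `$tissues`.
#' @examples
#' sim <- simulate_cohort(n_tissues = 3, genes = 40, samples_per_tissue = 15,
#'                        seed = 1)
#' fit <- dgd(sim$counts, tissues = sim$truth$tissue, latent_dim = 2,
#'            n_components = 4, hidden = c(8, 16),
#'            control = dgd_control(epochs = 20, batch_size = 16), seed = 1)
#' fit
#' @export
dgd <- function(x, tissues = NULL, latent_dim = 50, n_components = 45,
                hidden = c(500, 8000), dispersion_init = 2, beta_init = NULL,
                mean_floor = 1e-10, prior = dgd_prior(),
                control = dgd_control(), seed = NULL) {
  if (inherits(x, "dgd_counts") && is.null(tissues)) tissues <- x$tissues
  counts <- as_count_matrix(x)
  if (!is.null(seed)) set.seed(seed)
  object <- dgd_init(ncol(counts), nrow(counts), latent_dim, n_components,
                     hidden, dispersion_init, beta_init, mean_floor, prior,
                     genes = colnames(counts))
  object$tissues <- tissues
  object$seed <- seed
  dgd_train(object, counts, control)
}

#' Run the training loop on an initialized model
#'
#' Exposed separately from [dgd()] so optimization can be resumed or studied
#' in isolation; [dgd()] is `dgd_init()` followed by `dgd_train()`.
#'
#' @param object A `"dgd"` object (from [dgd_init()] or a previous fit).
#' @param x Count matrix aligned to `object$genes`.
#' @param control A [dgd_control()].
#' @return The trained `"dgd"` object.
#' @export
dgd_train <- function(object, x, control = dgd_control()) {
  counts <- as_count_matrix(x)
  n <- nrow(counts); G <- ncol(counts)
  if (G != length(object$genes)) stop_dgd("count matrix width must equal model gene count")
  if (nrow(object$representations) != n)
    stop_dgd("representation count must equal sample count")
  scale <- rowMeans(counts)
  if (any(scale <= 0)) stop_dgd("all-zero samples are not admissible (undefined scale)")

  Z <- object$representations
  decoder <- object$decoder
  gmm <- object$gmm
  log_r <- object$log_r
  prior <- object$prior
  betas <- control$betas

  opt_dec <- adam_init(decoder[c("W", "b")])
  opt_gmm <- adam_init(gmm[c("means", "beta", "logits")])
  opt_r <- adam_init(log_r)
  # per-sample Adam state for representations (each row steps once per epoch)
  rep_m <- Z * 0; rep_v <- Z * 0; rep_t <- integer(n)

  n_batches <- ceiling(n / control$batch_size)
  loss_hist <- matrix(NA_real_, control$epochs, 4L,
                      dimnames = list(NULL, c("total", "reconstruction", "latent", "prior")))

  check_finite <- function(x, group) {
    bad <- if (is.list(x)) !all(vapply(rapply(x, is.finite, how = "unlist"), all, TRUE))
           else any(!is.finite(x))
    if (bad) stop_dgd("non-finite gradient or loss in parameter group '", group,
                      "'; try smaller learning rates")
  }

  for (epoch in seq_len(control$epochs)) {
    ord <- sample.int(n)
    splits <- split(ord, ceiling(seq_along(ord) / control$batch_size))
    ep_recon <- 0; ep_latent <- 0; ep_prior <- 0
    for (idx in splits) {
      B <- length(idx)
      zb <- Z[idx, , drop = FALSE]
      xb <- counts[idx, , drop = FALSE]
      sb <- scale[idx]

      fwd <- decoder_forward(decoder, zb)
      M <- fwd$output * sb + object$mean_floor
      r_row <- matrix(exp(log_r), B, G, byrow = TRUE)

      ll <- nb_log_pmf(xb, M, r_row)
      lat <- gmm_log_density(zb, gmm)
      lp <- gmm_log_prior(gmm, prior)
      batch_loss <- -(sum(ll) + sum(lat)) / B - lp / n_batches
      check_finite(batch_loss, "objective")

      # ---- gradients (of the minimized objective) ----
      dM <- nb_dlogpmf_dm(xb, M, r_row)
      dY <- -(dM * sb) / B
      if (control$grad_clip > 0)
        dY <- pmin(pmax(dY, -control$grad_clip), control$grad_clip)
      bwd <- decoder_backward(decoder, fwd, dY)
      if (control$weight_decay > 0)
        bwd$W <- Map(function(gw, w) gw + control$weight_decay * w, bwd$W, decoder$W)
      g_logr <- -colSums(nb_dlogpmf_dlogr(xb, M, r_row)) / B
      g_z <- bwd$dZ - gmm_grad_z(zb, gmm) / B   # dZ already holds -1/B from dY
      gp_lik <- gmm_grad_params(zb, gmm)
      gp_pri <- gmm_grad_prior(gmm, prior)
      g_gmm <- list(means = -gp_lik$means / B - gp_pri$means / n_batches,
                    beta = -gp_lik$beta / B - gp_pri$beta / n_batches,
                    logits = -gp_lik$logits / B - gp_pri$logits / n_batches)
      check_finite(list(bwd$W, bwd$b), "decoder")
      check_finite(g_logr, "dispersion")
      check_finite(g_z, "representation")
      check_finite(g_gmm, "gmm")

      # ---- parameter updates, one optimizer per group ----
      st <- adam_step(decoder[c("W", "b")], list(W = bwd$W, b = bwd$b),
                      opt_dec, control$lr_decoder, betas)
      decoder$W <- st$params$W; decoder$b <- st$params$b; opt_dec <- st$state

      st <- adam_step(gmm[c("means", "beta", "logits")], g_gmm, opt_gmm,
                      control$lr_gmm, betas)
      gmm$means <- st$params$means; gmm$beta <- st$params$beta
      gmm$logits <- st$params$logits; opt_gmm <- st$state

      st <- adam_step(log_r, g_logr, opt_r, control$lr_dispersion, betas)
      log_r <- st$params; opt_r <- st$state

      # representations: per-row Adam with per-row step counts
      rep_t[idx] <- rep_t[idx] + 1L
      rep_m[idx, ] <- betas[1L] * rep_m[idx, , drop = FALSE] + (1 - betas[1L]) * g_z
      rep_v[idx, ] <- betas[2L] * rep_v[idx, , drop = FALSE] + (1 - betas[2L]) * g_z^2
      mhat <- rep_m[idx, , drop = FALSE] / (1 - betas[1L]^rep_t[idx])
      vhat <- rep_v[idx, , drop = FALSE] / (1 - betas[2L]^rep_t[idx])
      Z[idx, ] <- zb - control$lr_representation * mhat / (sqrt(vhat) + 1e-8)

      ep_recon <- ep_recon - sum(ll)
      ep_latent <- ep_latent - sum(lat)
      ep_prior <- ep_prior - lp / n_batches
    }
    # dead-output rescue: a gene whose rectified output is zero for samples
    # with positive counts receives no gradient through the ReLU mask and
    # can never recover; a small output-bias bump re-opens the gradient path
    if (control$revive_every > 0 && epoch %% control$revive_every == 0) {
      Yall <- decoder_forward(decoder, Z)$output
      dead <- colSums(Yall == 0 & counts > 0) > 0
      if (any(dead)) {
        nl <- length(decoder$b)
        decoder$b[[nl]][dead] <- decoder$b[[nl]][dead] + 0.05
      }
    }
    # revive idle components: an empty-cluster reseed, as in k-means/EM
    if (control$revive_every > 0 && epoch %% control$revive_every == 0 &&
        epoch <= 0.7 * control$epochs) {
      gam <- gmm_responsibilities(Z, gmm)
      share <- colSums(gam) / n
      idle <- which(share < control$revive_share / gmm$C)
      if (length(idle)) {
        dens <- gmm_log_density(Z, gmm)
        seeds <- order(dens)[seq_along(idle)]
        for (j in seq_along(idle)) {
          c_idx <- idle[j]
          gmm$means[c_idx, ] <- Z[seeds[j], ]
          gmm$beta[c_idx, ] <- prior$beta_mean + 1.5
          opt_gmm$m$means[c_idx, ] <- 0; opt_gmm$v$means[c_idx, ] <- 0
          opt_gmm$m$beta[c_idx, ] <- 0; opt_gmm$v$beta[c_idx, ] <- 0
        }
      }
    }
    loss_hist[epoch, ] <- c((ep_recon + ep_latent) / n + ep_prior,
                            ep_recon / n, ep_latent / n, ep_prior)
    if (control$verbose)
      message(sprintf("epoch %4d  loss %.4f", epoch, loss_hist[epoch, 1L]))
  }

  if (control$consolidate > 0)
    gmm <- consolidate_components(gmm, control$consolidate)

  if (control$dispersion_refit) {
    M <- decoder_forward(decoder, Z)$output * scale + object$mean_floor
    log_r <- vapply(seq_len(G), function(g) {
      stats::optimize(function(lr) sum(nb_log_pmf(counts[, g], M[, g], exp(lr))),
                      interval = c(log(1e-3), log(1e5)), maximum = TRUE,
                      tol = 1e-4)$maximum
    }, numeric(1))
  }

  object$decoder <- decoder
  object$gmm <- dgd_gmm(gmm$means, gmm$beta, gmm$logits)
  object$log_r <- log_r
  object$representations <- Z
  object$sample_scale <- scale
  object$sample_ids <- rownames(counts) %||% paste0("sample", seq_len(n))
  object$loss <- as.data.frame(cbind(epoch = seq_len(control$epochs), loss_hist))
  object$control <- control
  object$trained <- TRUE
  object
}
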